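# Internal helpers shared across modules: seeded evaluation and seed fan-out.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals never disturb
#' the caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage seed from a master seed
#'
#' One master seed fans out to per-stage / per-repeat / per-tree seeds by
#' stable hashing, so a single knob controls all randomness. The hash mixes
#' the master seed with a label (stage name, repeat index, ...) and maps
#' into `[1, 2^31 - 2]`.
#'
#' @param master_seed Integer master seed.
#' @param ... Labels (strings or integers) identifying the stream.
#' @return A single integer seed.
#' @export
derive_seed <- function(master_seed, ...) {
  labels <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- as.double(master_seed) %% 2147483647
  for (ch in utf8ToInt(labels)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h %% 2147483562 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mda <- function(fmt, ..., class) {
  stop(structure(
    class = c(class, "mda_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

# Guess the field separator of a delimited text file from its header line.
detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) return(",")
  if (grepl("\t", header)) "\t" else ","
}
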