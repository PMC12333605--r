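# Readers and writers for the three input tables (association edge list,
# similarity matrix, side-effect profiles) and their in-memory containers.
#
# Identifier matching is exact-string after whitespace trimming; catalogs
# preserve order of first appearance, and that order fixes row/column order
# in every downstream matrix.

#' Entity catalog
#'
#' An ordered set of unique entity identifiers (drugs or microbes) with a
#' name-to-position lookup. Position order is the order of first appearance
#' in the source file and is stable across save/load.
#'
#' @param ids Character vector of identifiers (whitespace is trimmed;
#'   duplicates collapse to the first occurrence).
#' @return An object of class `entity_catalog` with elements `ids`
#'   (character) and `index` (named integer, 1-based positions).
#' @export
entity_catalog <- function(ids) {
  ids <- trimws(as.character(ids))
  ids <- ids[!duplicated(ids)]
  if (any(!nzchar(ids))) {
    stop_mda("empty identifier in catalog", class = "mda_format_error")
  }
  index <- seq_along(ids)
  names(index) <- ids
  structure(list(ids = ids, index = index), class = "entity_catalog")
}

#' @export
length.entity_catalog <- function(x) length(x$ids)

#' @export
print.entity_catalog <- function(x, ...) {
  cat(sprintf("<entity_catalog: %d entities>\n", length(x$ids)))
  invisible(x)
}

#' Look up catalog positions of identifiers
#'
#' @param catalog An [entity_catalog()].
#' @param ids Character vector of identifiers.
#' @return Integer positions; errors on unknown identifiers.
#' @export
catalog_index <- function(catalog, ids) {
  ids <- trimws(as.character(ids))
  pos <- catalog$index[ids]
  if (anyNA(pos)) {
    stop_mda("unknown identifier(s): %s",
             paste(unique(ids[is.na(pos)]), collapse = ", "),
             class = "mda_lookup_error")
  }
  unname(pos)
}

#' Construct an association dataset from catalogs and a binary matrix
#'
#' @param drugs,microbes [entity_catalog()] objects.
#' @param A Binary matrix, `length(drugs) x length(microbes)`.
#' @return An `association_dataset`.
#' @export
new_association_dataset <- function(drugs, microbes, A) {
  stopifnot(inherits(drugs, "entity_catalog"), inherits(microbes, "entity_catalog"))
  A <- as.matrix(A)
  if (nrow(A) != length(drugs$ids) || ncol(A) != length(microbes$ids)) {
    stop_mda("adjacency dimensions do not match catalogs", class = "mda_format_error")
  }
  if (!all(A %in% c(0, 1))) {
    stop_mda("adjacency must be binary", class = "mda_format_error")
  }
  storage.mode(A) <- "double"
  dimnames(A) <- list(drugs$ids, microbes$ids)
  structure(list(drugs = drugs, microbes = microbes, A = A),
            class = "association_dataset")
}

#' @export
print.association_dataset <- function(x, ...) {
  cat(sprintf("<association_dataset: %d drugs x %d microbes, %d associations>\n",
              nrow(x$A), ncol(x$A), sum(x$A)))
  invisible(x)
}

#' Load a microbe-drug association table
#'
#' Reads a delimited edge list (one known association per row) and builds
#' the binary adjacency matrix `A` (`nd` drugs x `nm` microbes) with
#' `A[i, j] = 1` iff drug `i` is associated with microbe `j`. Duplicate rows
#' collapse to a single association. Comment lines starting with `#` may
#' pin the catalog order (as written by [save_dataset()]); otherwise catalog
#' order is order of first appearance.
#'
#' @param path Path to a TSV/CSV file with a header.
#' @param drug_col,microbe_col Column names holding drug and microbe
#'   identifiers.
#' @return An `association_dataset` with elements `drugs`, `microbes`
#'   (entity catalogs) and `A` (binary matrix).
#' @export
load_association_table <- function(path, drug_col = "drug", microbe_col = "microbe") {
  if (!file.exists(path)) {
    stop_mda("association file not found: %s", path, class = "mda_io_error")
  }
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          quote = "\"", stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (nrow(df) == 0L) {
    stop_mda("association table is empty: %s", path, class = "mda_empty_error")
  }
  for (col in c(drug_col, microbe_col)) {
    if (!col %in% names(df)) {
      stop_mda("column '%s' not present in %s", col, path,
               class = "mda_config_error")
    }
  }
  d_ids <- trimws(as.character(df[[drug_col]]))
  m_ids <- trimws(as.character(df[[microbe_col]]))

  drug_order <- parse_catalog_comment(meta, "drugs")
  microbe_order <- parse_catalog_comment(meta, "microbes")
  drugs <- entity_catalog(drug_order %||% d_ids)
  microbes <- entity_catalog(microbe_order %||% m_ids)

  A <- matrix(0, length(drugs$ids), length(microbes$ids))
  A[cbind(catalog_index(drugs, d_ids), catalog_index(microbes, m_ids))] <- 1
  new_association_dataset(drugs, microbes, A)
}

parse_catalog_comment <- function(meta, key) {
  pat <- paste0("^#\\s*", key, ":\t")
  hit <- meta[grepl(pat, meta)]
  if (length(hit) == 0L) return(NULL)
  strsplit(sub(pat, "", hit[[1L]]), "\t", fixed = TRUE)[[1L]]
}

#' Save an association dataset
#'
#' Writes the edge list plus comment headers pinning catalog order, so that
#' [load_association_table()] round-trips the object exactly (including
#' entities with no associations).
#'
#' @param dataset An `association_dataset`.
#' @param path Output path (TSV).
#' @return Invisibly, `path`.
#' @export
save_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "association_dataset"))
  idx <- which(dataset$A == 1, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  lines <- c(
    paste0("# drugs:\t", paste(dataset$drugs$ids, collapse = "\t")),
    paste0("# microbes:\t", paste(dataset$microbes$ids, collapse = "\t")),
    "drug\tmicrobe",
    paste(dataset$drugs$ids[idx[, 1L]], dataset$microbes$ids[idx[, 2L]], sep = "\t")
  )
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_mda("cannot write to %s", path, class = "mda_io_error")
  invisible(path)
}

#' Construct a similarity matrix container
#'
#' Validates symmetry (tolerance `1e-9`) and the `[0, 1]` range, and
#' forces the diagonal to 1 unless `force_diag = FALSE`.
#'
#' @param entities An [entity_catalog()].
#' @param S Square numeric matrix matching the catalog.
#' @param force_diag Set the diagonal to 1 (default `TRUE`).
#' @return A `similarity_matrix`.
#' @export
new_similarity_matrix <- function(entities, S, force_diag = TRUE) {
  S <- as.matrix(S)
  n <- length(entities$ids)
  if (nrow(S) != n || ncol(S) != n) {
    stop_mda("similarity matrix dimensions do not match catalog",
             class = "mda_format_error")
  }
  if (any(S < -1e-9) || any(S > 1 + 1e-9)) {
    stop_mda("similarity values outside [0, 1]", class = "mda_range_error")
  }
  S[S < 0] <- 0
  S[S > 1] <- 1
  if (max(abs(S - t(S))) > 1e-9) {
    stop_mda("similarity matrix not symmetric", class = "mda_symmetry_error")
  }
  if (force_diag) diag(S) <- 1
  dimnames(S) <- list(entities$ids, entities$ids)
  structure(list(entities = entities, S = S), class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix: %d x %d>\n", nrow(x$S), ncol(x$S)))
  invisible(x)
}

#' Load a similarity matrix
#'
#' Reads a square CSV with an identifier header row and identifier first
#' column. Small numerical asymmetry (at most `1e-6`) is symmetrized as
#' `(S + t(S)) / 2`; larger asymmetry is an error. The diagonal is forced to
#' 1 (self-similarity). When `expected` is given, rows/columns are reordered
#' to match it; entities missing from the file receive an all-zero
#' off-diagonal row/column (absent evidence) with diagonal 1.
#'
#' @param path Path to the CSV file.
#' @param expected Optional [entity_catalog()] giving the required
#'   row/column order.
#' @return A `similarity_matrix` with elements `entities` and `S`.
#' @export
load_similarity_matrix <- function(path, expected = NULL) {
  if (!file.exists(path)) {
    stop_mda("similarity file not found: %s", path, class = "mda_io_error")
  }
  df <- utils::read.csv(path, header = TRUE, row.names = 1L,
                        check.names = FALSE, stringsAsFactors = FALSE)
  S <- as.matrix(df)
  if (nrow(S) != ncol(S)) {
    stop_mda("similarity matrix is not square (%d x %d)", nrow(S), ncol(S),
             class = "mda_format_error")
  }
  rn <- trimws(rownames(S))
  cn <- trimws(colnames(S))
  if (!setequal(rn, cn)) {
    stop_mda("row and column identifier sets differ", class = "mda_format_error")
  }
  S <- S[, match(rn, cn), drop = FALSE]
  colnames(S) <- rn
  rownames(S) <- rn
  storage.mode(S) <- "double"
  if (any(S < -1e-9) || any(S > 1 + 1e-9)) {
    stop_mda("similarity values outside [0, 1] in %s", path,
             class = "mda_range_error")
  }
  asym <- max(abs(S - t(S)))
  if (asym > 1e-6) {
    stop_mda("similarity matrix asymmetry %.3g exceeds 1e-6", asym,
             class = "mda_symmetry_error")
  }
  S <- (S + t(S)) / 2

  if (is.null(expected)) {
    return(new_similarity_matrix(entity_catalog(rn), S))
  }
  n <- length(expected$ids)
  out <- diag(1, n)
  present <- expected$ids[expected$ids %in% rn]
  pidx <- catalog_index(expected, present)
  pos <- match(present, rn)
  out[pidx, pidx] <- S[pos, pos, drop = FALSE]
  dimnames(out) <- list(expected$ids, expected$ids)
  new_similarity_matrix(expected, out)
}

#' Save a similarity matrix
#'
#' Values are written with 17 significant digits so a save/load round trip
#' is bit-exact.
#'
#' @param sim A `similarity_matrix`.
#' @param path Output path (CSV).
#' @return Invisibly, `path`.
#' @export
save_matrix <- function(sim, path) {
  stopifnot(inherits(sim, "similarity_matrix"))
  ids <- sim$entities$ids
  body <- apply(sim$S, 1L, function(row) {
    paste(sprintf("%.17g", row), collapse = ",")
  })
  lines <- c(paste(c("", ids), collapse = ","), paste(ids, body, sep = ","))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_mda("cannot write to %s", path, class = "mda_io_error")
  invisible(path)
}

#' Load drug side-effect profiles
#'
#' Reads a two-column delimited file (drug identifier, side-effect term) and
#' returns set-valued profiles: each drug maps to the set of its terms.
#' Drugs absent from the file map to the empty set on lookup.
#'
#' @param path Path to a TSV/CSV with header `drug, side_effect`.
#' @return A `side_effect_profiles` object (named list of character sets).
#' @export
load_side_effects <- function(path) {
  if (!file.exists(path)) {
    stop_mda("side-effect file not found: %s", path, class = "mda_io_error")
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) <= 1L || all(!nzchar(trimws(lines[-1L])))) {
    return(structure(list(), class = "side_effect_profiles"))
  }
  sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  parts <- strsplit(body, sep, fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0L) {
    stop_mda("malformed side-effect line %d: '%s'", bad[[1L]] + 1L, body[[bad[[1L]]]],
             class = "mda_parse_error")
  }
  drug <- trimws(vapply(parts, `[[`, character(1), 1L))
  term <- trimws(vapply(parts, `[[`, character(1), 2L))
  profiles <- lapply(split(term, factor(drug, levels = unique(drug))), unique)
  structure(profiles, class = "side_effect_profiles")
}

#' Build side-effect profiles in memory
#'
#' @param profiles Named list: drug identifier -> character vector of terms.
#' @return A `side_effect_profiles` object.
#' @export
side_effect_profiles <- function(profiles) {
  structure(lapply(profiles, function(x) unique(trimws(as.character(x)))),
            class = "side_effect_profiles")
}

#' Look up a drug's side-effect set
#'
#' @param profiles A `side_effect_profiles` object.
#' @param drug Drug identifier.
#' @return Character vector of terms (empty if the drug has no recorded
#'   side effects).
#' @export
side_effects_of <- function(profiles, drug) {
  profiles[[trimws(drug)]] %||% character(0)
}

#' Save side-effect profiles
#'
#' @param profiles A `side_effect_profiles` object.
#' @param path Output path (TSV).
#' @return Invisibly, `path`.
#' @export
save_side_effects <- function(profiles, path) {
  stopifnot(inherits(profiles, "side_effect_profiles"))
  drugs <- names(profiles)
  rows <- unlist(lapply(drugs, function(d) {
    terms <- profiles[[d]]
    if (length(terms) == 0L) return(character(0))
    paste(d, terms, sep = "\t")
  }))
  ok <- tryCatch({ writeLines(c("drug\tside_effect", rows), path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_mda("cannot write to %s", path, class = "mda_io_error")
  invisible(path)
}
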