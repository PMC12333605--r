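# Pair feature construction and negative sampling.
#
# Each microbe-drug pair (d_u, m_v) is represented by the concatenation
# [row v of SM, row u of SD]: the microbe block first (length nm), then the
# drug block (length nd), total nm + nd. That order is recorded on every
# feature matrix so encoders and forests are never applied to a transposed
# layout.

#' Feature vector of a single microbe-drug pair
#'
#' @param u Drug position (1-based) in the drug catalog.
#' @param v Microbe position (1-based) in the microbe catalog.
#' @param sims An `integrated_similarities` object.
#' @return Numeric vector of length `nm + nd`: `SM[v, ]` followed by
#'   `SD[u, ]`.
#' @export
pair_vector <- function(u, v, sims) {
  stopifnot(inherits(sims, "integrated_similarities"))
  nd <- nrow(sims$SD)
  nm <- nrow(sims$SM)
  if (u < 1 || u > nd || v < 1 || v > nm) {
    stop_mda("pair index out of range: drug %d (nd=%d), microbe %d (nm=%d)",
             u, nd, v, nm, class = "mda_bounds_error")
  }
  unname(c(sims$SM[v, ], sims$SD[u, ]))
}

#' Feature matrix for a set of pairs
#'
#' Vectorized form of [pair_vector()]: one row per pair.
#'
#' @param pairs Data frame with integer columns `drug` and `microbe`
#'   (1-based catalog positions).
#' @param sims An `integrated_similarities` object.
#' @return Numeric matrix, `nrow(pairs)` x `(nm + nd)`, with attribute
#'   `layout = "microbe_first"`.
#' @export
pair_feature_matrix <- function(pairs, sims) {
  stopifnot(inherits(sims, "integrated_similarities"))
  nd <- nrow(sims$SD)
  nm <- nrow(sims$SM)
  if (any(pairs$drug < 1 | pairs$drug > nd | pairs$microbe < 1 | pairs$microbe > nm)) {
    stop_mda("pair index out of range", class = "mda_bounds_error")
  }
  X <- cbind(sims$SM[pairs$microbe, , drop = FALSE],
             sims$SD[pairs$drug, , drop = FALSE])
  dimnames(X) <- NULL
  attr(X, "layout") <- "microbe_first"
  X
}

#' Enumerate all microbe-drug pairs
#'
#' Produces the full `nd * nm` grid with labels taken from the adjacency
#' matrix: known associations get label 1, all other pairs are unlabeled
#' (`NA`). Pair order is drug-major (drug 1 with every microbe, then
#' drug 2, ...), and the row index of a pair is
#' `(drug - 1) * nm + microbe`.
#'
#' @param dataset An `association_dataset`.
#' @return Data frame with columns `drug`, `microbe` (1-based positions)
#'   and `label` (1 or `NA`).
#' @export
enumerate_pairs <- function(dataset) {
  stopifnot(inherits(dataset, "association_dataset"))
  nd <- nrow(dataset$A)
  nm <- ncol(dataset$A)
  pairs <- data.frame(
    drug = rep(seq_len(nd), each = nm),
    microbe = rep(seq_len(nm), times = nd)
  )
  lab <- dataset$A[cbind(pairs$drug, pairs$microbe)]
  pairs$label <- ifelse(lab == 1, 1, NA_real_)
  pairs
}

#' Uniform negative sampling
#'
#' Draws `n` distinct pairs uniformly without replacement from the
#' unlabeled pool and labels them 0.
#'
#' @param pool Data frame of unlabeled pairs (columns `drug`, `microbe`).
#' @param n Number of negatives.
#' @param seed Integer seed; the same seed reproduces the same draw.
#' @return `n`-row data frame with columns `drug`, `microbe`, `label` (0).
#' @export
sample_negatives_random <- function(pool, n, seed) {
  if (nrow(pool) < n) {
    stop_mda("unlabeled pool (%d) smaller than requested negatives (%d)",
             nrow(pool), n, class = "mda_sampling_error")
  }
  take <- with_seed(seed, sample.int(nrow(pool), n))
  out <- pool[take, c("drug", "microbe"), drop = FALSE]
  out$label <- 0
  rownames(out) <- NULL
  out
}

#' Density-aware stratified (DAS) negative sampling
#'
#' Each unlabeled pair's density is the number of other pool pairs whose
#' feature vectors lie within `radius` (Euclidean). The pool is sorted by
#' density (descending, ties broken by pair enumeration index) and sampled
#' systematically - indices `floor(k * |pool| / n) + 1` for
#' `k = 0..n-1` - so every density stratum is represented.
#'
#' With `radius = "auto"` the radius is the 25th percentile of pairwise
#' distances in a seeded subsample of `min(1000, |pool|)` pairs. For pools
#' larger than `cap`, densities are counted against a seeded subsample of
#' `cap` pairs (only the density ordering matters downstream);
#' `exact = TRUE` forces all-pairs counting.
#'
#' @param pool Data frame of unlabeled pairs (columns `drug`, `microbe`).
#' @param sims An `integrated_similarities` object (features are computed
#'   from it).
#' @param n Number of negatives.
#' @param radius Positive numeric radius, or `"auto"`.
#' @param seed Integer seed.
#' @param cap Reference-set cap for density counting (default 20000).
#' @param exact Force exact all-pairs density computation.
#' @return `n`-row data frame with columns `drug`, `microbe`, `label` (0).
#' @export
sample_negatives_das <- function(pool, sims, n, radius = "auto", seed = 1L,
                                 cap = 20000L, exact = FALSE) {
  m <- nrow(pool)
  if (m < n) {
    stop_mda("unlabeled pool (%d) smaller than requested negatives (%d)",
             m, n, class = "mda_sampling_error")
  }
  if (!identical(radius, "auto")) {
    if (!is.numeric(radius) || length(radius) != 1L || radius <= 0) {
      stop_mda("radius must be positive or 'auto'", class = "mda_config_error")
    }
  }
  X <- pair_feature_matrix(pool, sims)

  if (identical(radius, "auto")) {
    sub <- with_seed(derive_seed(seed, "das-radius"),
                     sample.int(m, min(1000L, m)))
    dd <- stats::dist(X[sub, , drop = FALSE])
    radius <- stats::quantile(dd, 0.25, names = FALSE)
    if (radius <= 0) radius <- max(dd) / 2 + 1e-12
  }

  if (exact || m <= cap) {
    ref <- seq_len(m)
  } else {
    ref <- sort(with_seed(derive_seed(seed, "das-ref"), sample.int(m, cap)))
  }
  density <- das_density(X, X[ref, , drop = FALSE], radius)
  # counting against a reference set includes self-matches for reference
  # members; subtract them so density counts *other* neighbours
  self_in_ref <- seq_len(m) %in% ref
  density <- density - as.numeric(self_in_ref)

  ord <- order(-density, seq_len(m))
  take <- ord[floor((seq_len(n) - 1) * m / n) + 1L]
  out <- pool[take, c("drug", "microbe"), drop = FALSE]
  out$label <- 0
  rownames(out) <- NULL
  attr(out, "radius") <- radius
  out
}

# Chunked neighbour counting: for each row of X, how many rows of ref_X lie
# within `radius` (Euclidean), including exact self-matches.
das_density <- function(X, ref_X, radius, chunk = 1000L) {
  r2 <- radius^2
  ref_sq <- rowSums(ref_X^2)
  m <- nrow(X)
  counts <- numeric(m)
  for (start in seq(1L, m, by = chunk)) {
    idx <- start:min(start + chunk - 1L, m)
    Xi <- X[idx, , drop = FALSE]
    d2 <- outer(rowSums(Xi^2), ref_sq, `+`) - 2 * (Xi %*% t(ref_X))
    counts[idx] <- rowSums(d2 <= r2 + 1e-12)
  }
  counts
}

#' Assemble a balanced training set
#'
#' Collects all known associations of `dataset` as positives, draws an
#' equal number of negatives from the unlabeled pairs (uniform or DAS
#' sampling), and attaches the raw pair feature matrix.
#'
#' @param dataset An `association_dataset` (the *training view*: held-out
#'   test associations must already be zeroed).
#' @param sims An `integrated_similarities` object.
#' @param sampler `"random"` or `"das"`.
#' @param seed Integer seed for the negative draw.
#' @param ... Passed to the sampler ([sample_negatives_das()] options).
#' @return A `training_set`: list with data frames `positives`,
#'   `negatives`, matrix `X` (features, positives first), numeric `y`,
#'   and `seed`.
#' @export
build_training_set <- function(dataset, sims, sampler = c("random", "das"),
                               seed = 1L, ...) {
  sampler <- match.arg(sampler)
  pairs <- enumerate_pairs(dataset)
  positives <- pairs[!is.na(pairs$label), c("drug", "microbe"), drop = FALSE]
  positives$label <- 1
  rownames(positives) <- NULL
  pool <- pairs[is.na(pairs$label), c("drug", "microbe"), drop = FALSE]
  n <- nrow(positives)
  negatives <- if (sampler == "random") {
    sample_negatives_random(pool, n, seed)
  } else {
    sample_negatives_das(pool, sims, n, seed = seed, ...)
  }
  both <- rbind(positives, negatives)
  X <- pair_feature_matrix(both, sims)
  structure(list(positives = positives, negatives = negatives,
                 X = X, y = both$label, seed = as.integer(seed)),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("<training_set: %d positives, %d negatives, %d features>\n",
              nrow(x$positives), nrow(x$negatives), ncol(x$X)))
  invisible(x)
}
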