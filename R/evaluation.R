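# Evaluation protocol: repeated five-fold cross-validation over known
# associations, rank-against-unlabeled AUC, precision-recall curves, the
# encoded-feature correlation diagnostic, and the per-drug ranking / drug
# masking case-study workflow.

#' Cross-validation configuration
#'
#' @param n_folds Folds (default 5).
#' @param n_repeats Repeats of the whole CV (default 10).
#' @param sampler Negative sampler: `"random"` or `"das"`.
#' @param encoder Encoder settings as a named list of
#'   [encoder_config()] arguments (e.g. `list(epochs = 20)`); `input_dim`
#'   and `seed` are filled in per fold.
#' @param brf A [brf_config()]; its seed is re-derived per fold.
#' @param master_seed Single seed from which folds, samplers, encoder and
#'   forest streams all derive.
#' @param neg_pool Negative pool for AUC: `"full"` (all pairs unlabeled in
#'   the complete dataset; default) or `"exclude_sampled"` (additionally
#'   drop the training-sampled negatives).
#' @param std_over Standard deviation over all `folds x repeats` AUCs
#'   (`"folds"`, default, population SD) or over repeat means
#'   (`"repeat_means"`).
#' @return A `cv_config` list.
#' @export
cv_config <- function(n_folds = 5L, n_repeats = 10L,
                      sampler = c("random", "das"),
                      encoder = list(), brf = brf_config(),
                      master_seed = 1L,
                      neg_pool = c("full", "exclude_sampled"),
                      std_over = c("folds", "repeat_means")) {
  sampler <- match.arg(sampler)
  neg_pool <- match.arg(neg_pool)
  std_over <- match.arg(std_over)
  if (n_folds < 2L) {
    stop_mda("n_folds must be >= 2", class = "mda_config_error")
  }
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 sampler = sampler, encoder = encoder, brf = brf,
                 master_seed = as.integer(master_seed),
                 neg_pool = neg_pool, std_over = std_over),
            class = "cv_config")
}

#' Rank-against-unlabeled AUC
#'
#' Mann-Whitney statistic: the probability that a positive outscores a
#' negative, counting ties as one half.
#'
#' @param pos_scores Scores of held-out known associations.
#' @param neg_scores Scores of the unlabeled pool.
#' @return AUC in `[0, 1]`.
#' @export
rank_auc <- function(pos_scores, neg_scores) {
  n1 <- length(pos_scores)
  n0 <- length(neg_scores)
  if (n1 == 0L || n0 == 0L) {
    stop_mda("both score sets must be non-empty", class = "mda_input_error")
  }
  r <- rank(c(pos_scores, neg_scores), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Partition known associations into CV folds
#'
#' Seeded shuffle followed by contiguous chunking; fold sizes differ by at
#' most one (earlier folds take the remainder).
#'
#' @param positives Data frame of known pairs (columns `drug`, `microbe`).
#' @param n_folds Number of folds.
#' @param seed Integer seed.
#' @return List of `n_folds` disjoint data frames whose union is
#'   `positives`.
#' @export
make_folds <- function(positives, n_folds, seed) {
  n <- nrow(positives)
  if (n < n_folds) {
    stop_mda("fewer positives (%d) than folds (%d)", n, n_folds,
             class = "mda_config_error")
  }
  ord <- with_seed(seed, sample.int(n))
  sizes <- rep(n %/% n_folds, n_folds)
  extra <- n %% n_folds
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-n_folds] + 1L)
  lapply(seq_len(n_folds), function(f) {
    out <- positives[ord[starts[f]:ends[f]], , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Train the full pipeline on a training view
#'
#' Builds the balanced training set, trains the encoder on raw pair
#' features, encodes the training set, and fits the BRF on the encodings.
#'
#' @param dataset Training-view `association_dataset` (test associations
#'   already zeroed, if any).
#' @param sims An `integrated_similarities` object.
#' @param sampler `"random"` or `"das"`.
#' @param encoder_args Named list of [encoder_config()] arguments.
#' @param brf_cfg A [brf_config()].
#' @param seed Integer seed for sampling, encoder, and forest streams.
#' @return An `mda_pipeline`: list with `encoder`, `forest`,
#'   `training_set`, and `sims` metadata.
#' @export
train_pipeline <- function(dataset, sims, sampler = "random",
                           encoder_args = list(), brf_cfg = brf_config(),
                           seed = 1L) {
  ts <- build_training_set(dataset, sims, sampler = sampler,
                           seed = derive_seed(seed, "negatives"))
  input_dim <- ncol(ts$X)
  enc_args <- utils::modifyList(list(input_dim = input_dim,
                                     seed = derive_seed(seed, "encoder")),
                                encoder_args)
  enc_cfg <- do.call(encoder_config, enc_args)
  encoder <- build_encoder(input_dim, enc_cfg)
  encoder <- train_encoder(encoder, ts$X, ts$y)
  E_train <- encode(encoder, ts$X)
  brf_cfg$seed <- derive_seed(seed, "forest")
  forest <- brf_fit(E_train, ts$y, brf_cfg)
  structure(list(encoder = encoder, forest = forest, training_set = ts),
            class = "mda_pipeline")
}

#' Score every microbe-drug pair
#'
#' @param pipeline An `mda_pipeline` from [train_pipeline()].
#' @param pairs Data frame of pairs (columns `drug`, `microbe`).
#' @param sims An `integrated_similarities` object.
#' @return Numeric score per pair row.
#' @export
score_pairs <- function(pipeline, pairs, sims) {
  X <- pair_feature_matrix(pairs, sims)
  brf_predict(pipeline$forest, encode(pipeline$encoder, X))
}

#' Run one cross-validation fold
#'
#' Zeroes the held-out associations in a training view, trains the full
#' pipeline on the remaining positives plus sampled negatives, scores all
#' pairs, and computes the rank-against-unlabeled AUC: held-out positives
#' against all pairs unlabeled in the *full* dataset (or additionally
#' excluding training-sampled negatives, per `config$neg_pool`).
#'
#' @param dataset Full `association_dataset`.
#' @param sims An `integrated_similarities` object.
#' @param test_pairs Data frame of held-out known associations.
#' @param config A [cv_config()].
#' @param seed Fold seed.
#' @return List with `auc`, `pos_scores`, `neg_scores`, `scores` (all
#'   pairs, in [enumerate_pairs()] order), and the trained `pipeline`.
#' @export
run_fold <- function(dataset, sims, test_pairs, config, seed) {
  nm <- ncol(dataset$A)
  train_view <- dataset
  train_view$A[cbind(test_pairs$drug, test_pairs$microbe)] <- 0

  pipeline <- train_pipeline(train_view, sims, sampler = config$sampler,
                             encoder_args = config$encoder,
                             brf_cfg = config$brf, seed = seed)
  all_pairs <- enumerate_pairs(dataset)
  scores <- score_pairs(pipeline, all_pairs, sims)

  pair_row <- function(p) (p$drug - 1L) * nm + p$microbe
  test_rows <- pair_row(test_pairs)
  neg_rows <- which(is.na(all_pairs$label))      # unlabeled in the FULL dataset
  if (config$neg_pool == "exclude_sampled") {
    neg_rows <- setdiff(neg_rows, pair_row(pipeline$training_set$negatives))
  }
  pos_scores <- scores[test_rows]
  neg_scores <- scores[neg_rows]
  list(auc = rank_auc(pos_scores, neg_scores),
       pos_scores = pos_scores, neg_scores = neg_scores,
       scores = scores, pipeline = pipeline)
}

#' Repeated k-fold cross-validation
#'
#' Repeats the fold protocol `n_repeats` times with fold assignments,
#' samplers, encoder and forest all seeded from `master_seed`, and pools
#' per-fold AUCs.
#'
#' @param dataset Full `association_dataset`.
#' @param sims An `integrated_similarities` object.
#' @param config A [cv_config()].
#' @param keep_curves Store ROC/PR points of each repeat's pooled scores
#'   (default `TRUE`).
#' @return A `cv_result`: `fold_aucs` (matrix repeats x folds),
#'   `mean_auc`, `std_auc`, per-repeat `roc` and `pr` point sets.
#' @export
cross_validate <- function(dataset, sims, config = cv_config(),
                           keep_curves = TRUE) {
  positives <- enumerate_pairs(dataset)
  positives <- positives[!is.na(positives$label), c("drug", "microbe")]
  rownames(positives) <- NULL

  fold_aucs <- matrix(NA_real_, config$n_repeats, config$n_folds)
  roc <- vector("list", config$n_repeats)
  pr <- vector("list", config$n_repeats)
  for (r in seq_len(config$n_repeats)) {
    folds <- make_folds(positives, config$n_folds,
                        derive_seed(config$master_seed, "folds", r))
    rep_pos <- numeric(0)
    rep_neg <- numeric(0)
    for (f in seq_len(config$n_folds)) {
      res <- run_fold(dataset, sims, folds[[f]], config,
                      derive_seed(config$master_seed, "fold", r, f))
      fold_aucs[r, f] <- res$auc
      if (keep_curves) {
        rep_pos <- c(rep_pos, res$pos_scores)
        rep_neg <- c(rep_neg, res$neg_scores)
      }
    }
    if (keep_curves) {
      roc[[r]] <- roc_curve(rep_pos, rep_neg)
      pr[[r]] <- pr_curve(rep_pos, rep_neg)
    }
  }
  aucs <- as.vector(t(fold_aucs))
  std <- if (config$std_over == "folds") {
    sqrt(mean((aucs - mean(aucs))^2))          # population SD over all folds
  } else {
    stats::sd(rowMeans(fold_aucs))
  }
  structure(list(fold_aucs = fold_aucs, mean_auc = mean(aucs), std_auc = std,
                 roc = roc, pr = pr, config = config),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result: %d repeats x %d folds, AUC %.4f +/- %.4f>\n",
              nrow(x$fold_aucs), ncol(x$fold_aucs), x$mean_auc, x$std_auc))
  invisible(x)
}

#' ROC curve points
#'
#' @param pos_scores,neg_scores Non-empty score vectors.
#' @return Data frame with `threshold`, `tpr`, `fpr` at every distinct
#'   threshold, descending.
#' @export
roc_curve <- function(pos_scores, neg_scores) {
  if (length(pos_scores) == 0L || length(neg_scores) == 0L) {
    stop_mda("both score sets must be non-empty", class = "mda_input_error")
  }
  th <- sort(unique(c(pos_scores, neg_scores)), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(pos_scores >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(neg_scores >= t), numeric(1))
  data.frame(threshold = th, tpr = tpr, fpr = fpr)
}

#' Precision-recall curve points
#'
#' Precision and recall at every distinct score threshold, in descending
#' threshold order; recall is monotone non-decreasing along the curve.
#'
#' @param pos_scores,neg_scores Non-empty score vectors.
#' @return Data frame with `threshold`, `recall`, `precision`.
#' @export
pr_curve <- function(pos_scores, neg_scores) {
  if (length(pos_scores) == 0L || length(neg_scores) == 0L) {
    stop_mda("both score sets must be non-empty", class = "mda_input_error")
  }
  th <- sort(unique(c(pos_scores, neg_scores)), decreasing = TRUE)
  n1 <- length(pos_scores)
  out <- lapply(th, function(t) {
    tp <- sum(pos_scores >= t)
    fp <- sum(neg_scores >= t)
    c(recall = tp / n1, precision = tp / (tp + fp))
  })
  out <- do.call(rbind, out)
  data.frame(threshold = th, recall = out[, "recall"],
             precision = out[, "precision"])
}

#' Correlation diagnostic for encoded features
#'
#' Pearson correlation matrix of the encoded feature columns, plus the
#' distribution of absolute off-diagonal values. Constant columns are
#' flagged and their correlations reported as 0 by convention.
#'
#' @param E Encoded feature matrix (>= 3 rows, >= 2 columns).
#' @return List with `correlation` (matrix), `constant_columns` (integer
#'   indices), and `summary` (quantiles + mean of absolute off-diagonal
#'   correlations).
#' @export
feature_correlation <- function(E) {
  E <- as.matrix(E)
  if (nrow(E) < 3L) {
    stop_mda("need at least 3 rows", class = "mda_input_error")
  }
  if (ncol(E) < 2L) {
    stop_mda("need at least 2 columns", class = "mda_input_error")
  }
  sds <- apply(E, 2L, stats::sd)
  constant <- which(sds == 0)
  R <- suppressWarnings(stats::cor(E))
  R[is.na(R)] <- 0
  diag(R) <- 1
  off <- abs(R[upper.tri(R)])
  list(correlation = R, constant_columns = constant,
       summary = c(mean = mean(off),
                   stats::quantile(off, c(0.5, 0.9, 0.99))))
}

#' Mask a drug's associations (new-drug protocol)
#'
#' Returns a copy of the dataset with the given drug's adjacency row set
#' to zero; the original is untouched. Masking is idempotent.
#'
#' @param dataset An `association_dataset`.
#' @param drug Drug identifier.
#' @return The masked `association_dataset`.
#' @export
mask_drug <- function(dataset, drug) {
  i <- catalog_index(dataset$drugs, drug)
  dataset$A[i, ] <- 0
  dataset
}

#' Rank candidate microbes for a drug
#'
#' Scores every (drug, microbe) pair that is not a known positive in the
#' training view and returns the top `k` by descending score, ties broken
#' by microbe index.
#'
#' @param pipeline A trained `mda_pipeline`.
#' @param dataset The training-view `association_dataset` the pipeline was
#'   trained on (its known positives are excluded from ranking).
#' @param sims An `integrated_similarities` object.
#' @param drug Drug identifier.
#' @param k Number of candidates to return (default 50); truncated with a
#'   warning when fewer candidates exist.
#' @return A `ranked_predictions` data frame with columns `rank`,
#'   `microbe`, `score`.
#' @export
rank_microbes_for_drug <- function(pipeline, dataset, sims, drug, k = 50L) {
  u <- catalog_index(dataset$drugs, drug)
  nm <- ncol(dataset$A)
  candidates <- which(dataset$A[u, ] == 0)
  if (length(candidates) < k) {
    warning(sprintf("only %d candidate microbes available; truncating k = %d",
                    length(candidates), k))
    k <- length(candidates)
  }
  pairs <- data.frame(drug = rep(u, length(candidates)), microbe = candidates)
  s <- score_pairs(pipeline, pairs, sims)
  ord <- order(-s, candidates)
  top <- ord[seq_len(k)]
  out <- data.frame(rank = seq_len(k),
                    microbe = dataset$microbes$ids[candidates[top]],
                    score = s[top])
  class(out) <- c("ranked_predictions", "data.frame")
  attr(out, "drug") <- dataset$drugs$ids[u]
  out
}
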