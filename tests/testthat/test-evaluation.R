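test_that("rank AUC matches brute-force pair counting and pROC", {
  # worked example: 3 positives (0.9, 0.8, 0.4) vs 2 negatives (0.5, 0.1)
  expect_equal(rank_auc(c(0.9, 0.8, 0.4), c(0.5, 0.1)), 5 / 6)
  # bounds and tie handling
  expect_equal(rank_auc(rep(1, 3), rep(0, 4)), 1)
  expect_equal(rank_auc(rep(0.7, 5), rep(0.7, 9)), 0.5)
  # random instances vs the enumeration oracle and an independent library
  for (case in 1:15) {
    set.seed(700 + case)
    pos <- round(runif(sample(3:50, 1)), 2)     # rounding forces ties
    neg <- round(runif(sample(3:50, 1)), 2)
    a <- rank_auc(pos, neg)
    expect_equal(a, oracle_auc(pos, neg), info = paste("case", case))
    proc_auc <- as.numeric(pROC::auc(
      c(rep(1, length(pos)), rep(0, length(neg))), c(pos, neg),
      direction = "<", quiet = TRUE))
    expect_equal(a, proc_auc, tolerance = 1e-12, info = paste("case", case))
  }
  expect_error(rank_auc(numeric(0), 1), class = "mda_input_error")
})

test_that("fold construction partitions positives with near-equal sizes", {
  pos <- data.frame(drug = rep(1:11, each = 1), microbe = 1:11)
  folds <- make_folds(pos, 5, seed = 8)
  expect_equal(sort(sapply(folds, nrow), decreasing = TRUE), c(3, 2, 2, 2, 2))
  keys <- unlist(lapply(folds, function(f) paste(f$drug, f$microbe)))
  expect_setequal(keys, paste(pos$drug, pos$microbe))
  expect_equal(anyDuplicated(keys), 0L)
  expect_identical(folds, make_folds(pos, 5, seed = 8))
  # 2,470 positives over 5 folds -> five folds of 494
  big <- data.frame(drug = seq_len(2470), microbe = 1L)
  expect_equal(unique(sapply(make_folds(big, 5, 1), nrow)), 494L)
  expect_error(make_folds(pos[1:3, ], 5, 1), class = "mda_config_error")
})

test_that("precision-recall and ROC points match a threshold-sweep oracle", {
  # spec'd micro-example
  pts <- pr_curve(c(0.9, 0.4), 0.6)
  expect_equal(pts$threshold, c(0.9, 0.6, 0.4))
  expect_equal(pts$recall, c(0.5, 0.5, 1))
  expect_equal(pts$precision, c(1, 0.5, 2 / 3))
  # perfect separation holds precision 1 everywhere
  perf <- pr_curve(c(0.8, 0.9), c(0.1, 0.2))
  expect_true(all(perf$precision[perf$recall <= 1 & perf$threshold > 0.2] == 1))
  # constant scores collapse to a single point at the prevalence
  const <- pr_curve(rep(0.5, 3), rep(0.5, 9))
  expect_equal(nrow(const), 1)
  expect_equal(const$precision, 0.25)
  expect_equal(const$recall, 1)
  # random cases vs oracle; recall is monotone along the curve
  for (case in 1:10) {
    set.seed(800 + case)
    pos <- round(runif(sample(3:40, 1)), 2)
    neg <- round(runif(sample(3:40, 1)), 2)
    got <- pr_curve(pos, neg)
    ref <- oracle_pr(pos, neg)
    expect_equal(got$recall, ref$recall, info = paste("case", case))
    expect_equal(got$precision, ref$precision, info = paste("case", case))
    expect_true(all(diff(got$recall) >= 0))
    roc <- roc_curve(pos, neg)
    expect_true(all(diff(roc$tpr) >= 0) && all(diff(roc$fpr) >= 0))
  }
  expect_error(pr_curve(numeric(0), 1), class = "mda_input_error")
})

test_that("feature correlation flags constant columns and bounds noise", {
  set.seed(31)
  E <- matrix(rnorm(10000 * 4), 10000, 4)
  fc <- feature_correlation(E)
  expect_equal(dim(fc$correlation), c(4L, 4L))
  expect_lt(fc$summary[["mean"]], 0.05)         # independent columns
  # duplicated column -> off-diagonal correlation 1
  E2 <- cbind(E[, 1], E[, 1], E[, 2])
  expect_equal(feature_correlation(E2)$correlation[1, 2], 1)
  # constant column -> flagged, correlations reported 0
  E3 <- cbind(E[, 1:2], 0.7)
  fc3 <- feature_correlation(E3)
  expect_equal(fc3$constant_columns, 3L)
  expect_equal(unname(fc3$correlation[3, 1:2]), c(0, 0))
  expect_error(feature_correlation(E[1:2, ]), class = "mda_input_error")
})

test_that("drug masking zeroes one row, idempotently, without touching the rest", {
  synth <- tiny_synth()
  d <- synth$dataset
  drug <- d$drugs$ids[[which.max(rowSums(d$A))]]
  k <- sum(d$A[drug, ])
  masked <- mask_drug(d, drug)
  expect_equal(sum(masked$A[drug, ]), 0)
  expect_equal(sum(d$A) - sum(masked$A), k)
  expect_identical(masked$A[-catalog_index(d$drugs, drug), ],
                   d$A[-catalog_index(d$drugs, drug), ])
  expect_identical(mask_drug(masked, drug), masked)
  expect_error(mask_drug(d, "nonexistent"), class = "mda_lookup_error")
})

test_that("a fold run scores test positives against the full unlabeled pool", {
  synth <- tiny_synth()
  sims <- tiny_sims(synth)
  pos <- enumerate_pairs(synth$dataset)
  pos <- pos[!is.na(pos$label), c("drug", "microbe")]
  rownames(pos) <- NULL
  cfg <- tiny_cv_config()
  folds <- make_folds(pos, cfg$n_folds, seed = 17)
  res <- run_fold(synth$dataset, sims, folds[[1]], cfg, seed = 19)

  expect_length(res$pos_scores, nrow(folds[[1]]))
  n_unlabeled <- sum(synth$dataset$A == 0)
  expect_length(res$neg_scores, n_unlabeled)
  expect_true(all(res$scores >= 0 & res$scores <= 1))
  expect_equal(res$auc, rank_auc(res$pos_scores, res$neg_scores))
  # fold AUC arithmetic agrees with brute-force pair counting (<= 100 scores)
  expect_equal(rank_auc(res$pos_scores, res$neg_scores[1:80]),
               oracle_auc(res$pos_scores, res$neg_scores[1:80]))

  # leakage: no held-out positive carries label 1 in the fold's training set
  ts <- res$pipeline$training_set
  test_keys <- paste(folds[[1]]$drug, folds[[1]]$microbe)
  train_pos_keys <- paste(ts$positives$drug, ts$positives$microbe)
  expect_length(intersect(test_keys, train_pos_keys), 0)

  # exclude_sampled mode drops exactly the training negatives from the pool
  # (a sampled negative can be a held-out positive, which was never in the
  # full-dataset unlabeled pool to begin with)
  cfg2 <- tiny_cv_config(neg_pool = "exclude_sampled")
  res2 <- run_fold(synth$dataset, sims, folds[[1]], cfg2, seed = 19)
  negs <- res2$pipeline$training_set$negatives
  sampled_unlabeled <- sum(synth$dataset$A[cbind(negs$drug, negs$microbe)] == 0)
  expect_length(res2$neg_scores, n_unlabeled - sampled_unlabeled)
})

test_that("cross-validation is deterministic and leak-free across folds", {
  synth <- tiny_synth()
  sims <- tiny_sims(synth)
  cfg <- tiny_cv_config(master_seed = 23)
  cv1 <- cross_validate(synth$dataset, sims, cfg, keep_curves = TRUE)
  cv2 <- cross_validate(synth$dataset, sims, cfg, keep_curves = TRUE)
  expect_identical(cv1, cv2)
  expect_equal(dim(cv1$fold_aucs), c(1L, 5L))
  expect_true(all(cv1$fold_aucs >= 0 & cv1$fold_aucs <= 1))
  aucs <- as.vector(cv1$fold_aucs)
  expect_equal(cv1$mean_auc, mean(aucs))
  expect_equal(cv1$std_auc, sqrt(mean((aucs - mean(aucs))^2)))
  expect_s3_class(cv1$pr[[1]], "data.frame")
})

test_that("per-drug ranking excludes known positives and breaks ties by index", {
  synth <- tiny_synth()
  sims <- tiny_sims(synth)
  # short training can trip the soft undertraining warning; irrelevant here
  pipeline <- suppressWarnings(
    train_pipeline(synth$dataset, sims, encoder_args = list(epochs = 5L),
                   brf_cfg = brf_config(n_trees = 10L), seed = 29))
  drug <- synth$dataset$drugs$ids[[which.max(rowSums(synth$dataset$A))]]
  known <- synth$dataset$microbes$ids[synth$dataset$A[drug, ] == 1]
  top <- rank_microbes_for_drug(pipeline, synth$dataset, sims, drug, k = 5)
  expect_equal(nrow(top), 5)
  expect_length(intersect(top$microbe, known), 0)
  expect_true(all(diff(top$score) <= 0))
  # k larger than the candidate set truncates with a warning
  expect_warning(
    full <- rank_microbes_for_drug(pipeline, synth$dataset, sims, drug, k = 50),
    "truncat")
  expect_equal(nrow(full), sum(synth$dataset$A[drug, ] == 0))
  # masking makes the drug's known associates candidates again
  masked <- mask_drug(synth$dataset, drug)
  pipeline_m <- train_pipeline(masked, sims,
                               encoder_args = list(epochs = 5L),
                               brf_cfg = brf_config(n_trees = 10L), seed = 29)
  expect_warning(
    top_m <- rank_microbes_for_drug(pipeline_m, masked, sims, drug,
                                    k = ncol(masked$A)), NA)
  expect_true(all(known %in% top_m$microbe))
})
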