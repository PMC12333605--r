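test_that("structural/estimation split is a seeded disjoint cover with round-half-up", {
  s <- split_structural_estimation(1:10, 0.5, seed = 3)
  expect_length(s$structural, 5)
  expect_length(s$estimation, 5)
  expect_setequal(c(s$structural, s$estimation), 1:10)
  # odd n rounds half up: 11 * 0.5 -> 6 structural
  s11 <- split_structural_estimation(1:11, 0.5, seed = 3)
  expect_length(s11$structural, 6)
  expect_length(s11$estimation, 5)
  expect_identical(s11, split_structural_estimation(1:11, 0.5, seed = 3))
  expect_error(split_structural_estimation(1L, 0.5, seed = 1),
               class = "mda_degenerate_error")
})

test_that("candidate-feature counts follow the B1 Bernoulli trial", {
  # deterministic sizes at the extremes
  set.seed(1)
  expect_length(select_candidate_features(100, p1 = 1), 1)
  expect_length(select_candidate_features(100, p1 = 0), 10)    # ceiling(sqrt(100))
  expect_length(select_candidate_features(30, p1 = 0), 6)      # ceiling(sqrt(30))
  expect_equal(select_candidate_features(1, p1 = 0.5), 1)
  # empirical single-feature rate over 10,000 seeded trials: p1 +/- 3 sigma
  p1 <- 0.3
  n_trials <- 10000
  singles <- with(list(), {
    set.seed(2024)
    sum(replicate(n_trials, length(select_candidate_features(50, p1)) == 1))
  })
  sigma <- sqrt(p1 * (1 - p1) / n_trials)
  expect_lt(abs(singles / n_trials - p1), 3 * sigma)
})

test_that("split-point selection follows the B2 trial and the Gini oracle", {
  # two-point node: the only midpoint separates perfectly
  X <- matrix(c(0, 1), 2, 1)
  y <- c(0, 1)
  set.seed(5)
  sp <- choose_split(X, y, candidates = 1L, p2 = 0)
  expect_equal(sp$feature, 1L)
  expect_equal(sp$threshold, 0.5)
  expect_equal(sp$method, "impurity")
  # all-constant candidates are unsplittable
  expect_null(choose_split(matrix(1, 4, 2), c(0, 1, 0, 1), 1:2, p2 = 0))
  # random split stays inside the observed range
  Xr <- matrix(seq(0.2, 0.8, length.out = 10), 10, 1)
  set.seed(6)
  spr <- choose_split(Xr, rep(c(0, 1), 5), candidates = 1L, p2 = 1)
  expect_equal(spr$method, "random")
  expect_gt(spr$threshold, 0.2)
  expect_lt(spr$threshold, 0.8)
  # empirical random-split rate over 10,000 trials: p2 +/- 3 sigma
  p2 <- 0.3
  n_trials <- 10000
  set.seed(2025)
  Xn <- matrix(runif(20), 10, 2)
  yn <- rep(c(0, 1), 5)
  randoms <- sum(replicate(n_trials,
    choose_split(Xn, yn, 1:2, p2)$method == "random"))
  sigma <- sqrt(p2 * (1 - p2) / n_trials)
  expect_lt(abs(randoms / n_trials - p2), 3 * sigma)
  # exhaustive-search branch agrees with a brute-force Gini scan
  for (case in 1:10) {
    set.seed(3000 + case)
    n <- sample(5:30, 1)
    Xc <- matrix(runif(n * 3), n, 3)
    yc <- rbinom(n, 1, 0.5)
    if (length(unique(yc)) < 2) next
    sp <- choose_split(Xc, yc, 1:3, p2 = 0)
    best <- NULL
    for (j in 1:3) {
      vals <- sort(unique(Xc[, j]))
      if (length(vals) < 2) next
      for (i in seq_len(length(vals) - 1)) {
        thr <- (vals[i] + vals[i + 1]) / 2
        l <- yc[Xc[, j] <= thr]; r <- yc[Xc[, j] > thr]
        g <- (length(l) * 2 * mean(l) * (1 - mean(l)) +
              length(r) * 2 * mean(r) * (1 - mean(r))) / n
        if (is.null(best) || g < best$g - 1e-12) best <- list(j = j, thr = thr, g = g)
      }
    }
    expect_equal(sp$feature, best$j, info = paste("case", case))
    expect_equal(sp$threshold, best$thr, info = paste("case", case))
  }
})

test_that("tree growth stops on purity, depth, and unsplittable nodes", {
  cfg <- brf_config(min_split = 2L, p1 = 0, p2 = 0, seed = 1)
  X <- matrix(c(0.1, 0.2, 0.8, 0.9), 4, 1)
  # pure structural node -> single leaf
  set.seed(1)
  t_pure <- grow_tree(X, rep(1, 4), 1:4, 1:4, cfg)
  expect_equal(t_pure$type, "leaf")
  expect_equal(t_pure$positive_fraction, 1)
  # separable data, impurity branch -> depth-1 tree with leaf fractions 0 / 1
  y <- c(0, 0, 1, 1)
  set.seed(1)
  t_sep <- grow_tree(X, y, 1:4, 1:4, cfg)
  expect_equal(t_sep$type, "split")
  expect_equal(t_sep$threshold, 0.5)
  expect_equal(t_sep$left$positive_fraction, 0)
  expect_equal(t_sep$right$positive_fraction, 1)
  # depth cap 0 -> root leaf carrying the global estimation fraction
  cfg0 <- brf_config(max_depth = 0L, seed = 1)
  set.seed(1)
  t_root <- grow_tree(X, y, 1:4, 1:4, cfg0)
  expect_equal(t_root$type, "leaf")
  expect_equal(t_root$positive_fraction, 0.5)
  expect_error(grow_tree(X, y, integer(0), 1:4, cfg),
               class = "mda_degenerate_error")
})

test_that("leaves are filled by estimation samples only", {
  set.seed(9)
  n <- 60
  X <- matrix(runif(n * 3), n, 3)
  y <- as.numeric(X[, 1] > 0.5)
  struct_idx <- 1:30
  est_idx <- 31:60
  cfg <- brf_config(min_split = 5L, p1 = 0, p2 = 0, seed = 1)
  set.seed(4)
  t1 <- grow_tree(X, y, struct_idx, est_idx, cfg)
  # flipping estimation labels (structural fixed, same rng) keeps the shape
  y2 <- y
  y2[est_idx] <- 1 - y2[est_idx]
  set.seed(4)
  t2 <- grow_tree(X, y2, struct_idx, est_idx, cfg)
  expect_identical(tree_structure_hash(t1), tree_structure_hash(t2))
  # ...but changes leaf fractions
  leaf_fracs <- function(nd) {
    if (nd$type == "leaf") return(nd$positive_fraction)
    c(leaf_fracs(nd$left), leaf_fracs(nd$right))
  }
  expect_false(identical(leaf_fracs(t1), leaf_fracs(t2)))
  # flipping structural labels changes the shape (sanity of the hash)
  y3 <- y
  y3[struct_idx] <- rev(y3[struct_idx])
  set.seed(4)
  t3 <- grow_tree(X, y3, struct_idx, est_idx, cfg)
  expect_false(identical(tree_structure_hash(t1), tree_structure_hash(t3)))
})

test_that("forest fitting is seeded and learns a planted signal", {
  set.seed(21)
  n <- 200
  X <- matrix(runif(n * 5), n, 5)
  y <- as.numeric(X[, 2] + 0.3 * X[, 4] > 0.8)
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  cfg <- brf_config(n_trees = 30L, seed = 42)
  m1 <- brf_fit(X, y, cfg)
  m2 <- brf_fit(X, y, cfg)
  expect_equal(length(m1$trees), 30)
  expect_identical(m1, m2)                      # same seed -> same forest
  s <- brf_predict(m1, X)
  expect_true(all(s >= 0 & s <= 1))
  expect_gt(rank_auc(s[y == 1], s[y == 0]), 0.9)
  expect_error(brf_fit(X, rep(1, n), cfg), class = "mda_training_error")
  expect_error(brf_predict(m1, X[, 1:3]), class = "mda_shape_error")
  m_one <- brf_fit(X, y, brf_config(n_trees = 1L, seed = 7))
  expect_length(m_one$trees, 1)
})

test_that("predictions average leaf fractions across trees", {
  # hand-built forest: two stumps voting 1.0 and 0.0 -> score 0.5
  leaf <- function(f) list(type = "leaf", positive_fraction = f,
                           estimation_count = 1L)
  stump <- function(f_left, f_right) {
    list(type = "split", feature = 1L, threshold = 0.5,
         left = leaf(f_left), right = leaf(f_right))
  }
  model <- structure(list(trees = list(stump(1, 0), stump(0, 1)),
                          config = brf_config(n_trees = 2L),
                          n_features = 1L), class = "brf_model")
  expect_equal(brf_predict(model, matrix(0.2, 1, 1)), 0.5)
  expect_equal(brf_predict(model, matrix(0.9, 1, 1)), 0.5)
  model$trees <- list(stump(1, 0), stump(1, 0))
  expect_equal(brf_predict(model, matrix(c(0.2, 0.9), 2, 1)), c(1, 0))
})

test_that("the degenerate limit reproduces a reference Gini/sqrt(D) tree", {
  # p1 = p2 = 0, no bootstrap, structural = estimation = full sample:
  # each BRF tree must equal an independently implemented CART-style tree
  # consuming the same rng stream.
  for (case in 1:8) {
    set.seed(500 + case)
    n <- sample(20:50, 1)
    D <- sample(2:5, 1)
    X <- matrix(runif(n * D), n, D)
    y <- as.numeric(X[, 1] + 0.5 * runif(n) > 0.8)
    if (length(unique(y)) < 2) next
    seed <- 600 + case
    cfg <- brf_config(n_trees = 1L, p1 = 0, p2 = 0, bootstrap = FALSE,
                      structural_fraction = 1, min_split = 10L,
                      max_depth = 25L, seed = seed)
    model <- brf_fit(X, y, cfg)
    ref <- oracle_cart_tree(X, y, seed, min_split = 10L, max_depth = 25L)
    expect_identical(tree_structure_hash(model$trees[[1]]),
                     tree_structure_hash(ref),
                     info = paste("case", case))
    s_pkg <- brf_predict(model, X)
    s_ref <- apply(X, 1, function(x) oracle_route(ref, x))
    expect_equal(s_pkg, s_ref, info = paste("case", case))
  }
})

test_that("score spread across refits shrinks as the forest grows", {
  set.seed(13)
  n <- 120
  X <- matrix(runif(n * 4), n, 4)
  y <- as.numeric(X[, 1] > 0.5)
  probe <- matrix(runif(20 * 4), 20, 4)
  spread <- function(n_trees) {
    scores <- sapply(1:6, function(s) {
      brf_predict(brf_fit(X, y, brf_config(n_trees = n_trees, seed = s)), probe)
    })
    mean(apply(scores, 1, var))
  }
  expect_lt(spread(100), spread(10))
})
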