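# Bernoulli Random Forest (BRF), implemented from scratch.
#
# BRF differs from a classical random forest in three ways:
#   1. Each tree's (optionally bootstrapped) sample is divided into a
#      *structural* part, which shapes the tree, and an *estimation* part,
#      used only to fill leaf class fractions -- never to choose splits.
#   2. At each node a Bernoulli trial B1 (probability p1) decides whether a
#      single candidate feature is drawn, or ceiling(sqrt(D)) candidates.
#   3. A second Bernoulli trial B2 (probability p2) decides whether the
#      split point is drawn uniformly at random within a candidate's value
#      range, or chosen by exhaustive Gini-impurity search over midpoints.
#
# Routing convention: feature value <= threshold goes left. Impurity ties
# break on lowest feature index, then smallest threshold. Leaves with no
# estimation sample inherit the fraction of the nearest ancestor that has
# one (root fallback: the tree's global estimation fraction).

#' BRF configuration
#'
#' @param n_trees Number of trees (default 100).
#' @param p1 Probability that a node draws a single candidate feature
#'   (otherwise `ceiling(sqrt(D))` candidates). Default 0.05.
#' @param p2 Probability that a node picks its split point uniformly at
#'   random (otherwise by Gini search). Default 0.05.
#' @param min_split Minimum structural samples to attempt a split
#'   (default 10).
#' @param max_depth Depth cap (default 25; depth 0 = root leaf).
#' @param bootstrap Draw each tree's sample with replacement (default
#'   `TRUE`).
#' @param structural_fraction Fraction of the per-tree sample assigned to
#'   the structural part (default 0.5). The boundary value 1 is an explicit
#'   degenerate mode where structural = estimation = the full sample,
#'   matching a classical random-forest tree when `p1 = p2 = 0`.
#' @param seed Integer seed; tree `t` uses an independent stream derived
#'   from `(seed, t)`.
#' @return A `brf_config` list.
#' @export
brf_config <- function(n_trees = 100L, p1 = 0.05, p2 = 0.05, min_split = 10L,
                       max_depth = 25L, bootstrap = TRUE,
                       structural_fraction = 0.5, seed = 1L) {
  if (p1 < 0 || p1 > 1 || p2 < 0 || p2 > 1) {
    stop_mda("p1 and p2 must lie in [0, 1]", class = "mda_config_error")
  }
  if (structural_fraction <= 0 || structural_fraction > 1) {
    stop_mda("structural_fraction must lie in (0, 1]", class = "mda_config_error")
  }
  if (n_trees < 1L) {
    stop_mda("n_trees must be >= 1", class = "mda_config_error")
  }
  structure(list(n_trees = as.integer(n_trees), p1 = p1, p2 = p2,
                 min_split = as.integer(min_split),
                 max_depth = as.integer(max_depth),
                 bootstrap = isTRUE(bootstrap),
                 structural_fraction = structural_fraction,
                 seed = as.integer(seed)),
            class = "brf_config")
}

#' Split a sample into structural and estimation parts
#'
#' A seeded shuffle assigns `round-half-up(fraction * n)` indices to the
#' structural part and the rest to the estimation part.
#'
#' @param sample_indices Integer vector of sample indices (length >= 2).
#' @param structural_fraction Fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with integer vectors `structural` and `estimation`
#'   (disjoint, covering the input).
#' @export
split_structural_estimation <- function(sample_indices, structural_fraction,
                                        seed) {
  n <- length(sample_indices)
  if (n < 2L) {
    stop_mda("need at least 2 samples to split", class = "mda_degenerate_error")
  }
  n_struct <- floor(structural_fraction * n + 0.5)
  n_struct <- max(1L, min(n - 1L, n_struct))
  shuffled <- with_seed(seed, sample(sample_indices))
  list(structural = shuffled[seq_len(n_struct)],
       estimation = shuffled[(n_struct + 1L):n])
}

#' Draw candidate features for a node split (trial B1)
#'
#' With probability `p1` a single uniformly chosen feature is returned;
#' otherwise `ceiling(sqrt(D))` distinct features. Draws from the current
#' RNG stream.
#'
#' @param D Number of features.
#' @param p1 Single-feature probability.
#' @return Integer vector of candidate feature indices.
#' @export
select_candidate_features <- function(D, p1) {
  stopifnot(D >= 1L)
  k <- if (stats::runif(1) < p1) 1L else min(as.integer(ceiling(sqrt(D))), D)
  sort(sample.int(D, k))
}

#' Choose a split for a node (trial B2)
#'
#' With probability `p2` a non-constant candidate feature is drawn
#' uniformly and the threshold drawn uniformly inside its value range at
#' the node; otherwise the (feature, midpoint) pair minimizing weighted
#' Gini impurity over all candidates is chosen. Returns `NULL` when every
#' candidate is constant within the node.
#'
#' @param X_node Structural feature matrix at the node.
#' @param y_node Structural labels (0/1) at the node.
#' @param candidates Candidate feature indices.
#' @param p2 Random-split probability.
#' @return `NULL`, or a list `(feature, threshold, method)` with `method`
#'   `"random"` or `"impurity"`.
#' @export
choose_split <- function(X_node, y_node, candidates, p2) {
  ranges <- vapply(candidates, function(j) range(X_node[, j]), numeric(2))
  varying <- candidates[ranges[1L, ] < ranges[2L, ]]
  if (length(varying) == 0L) return(NULL)
  use_random <- stats::runif(1) < p2
  if (use_random) {
    j <- varying[[if (length(varying) == 1L) 1L else sample.int(length(varying), 1L)]]
    lo <- min(X_node[, j]); hi <- max(X_node[, j])
    return(list(feature = j, threshold = stats::runif(1, lo, hi),
                method = "random"))
  }
  best <- NULL
  best_gini <- Inf
  n <- length(y_node)
  for (j in sort(varying)) {
    v <- X_node[, j]
    ord <- order(v)
    vs <- v[ord]
    ys <- y_node[ord]
    new_val <- which(diff(vs) > 0)          # boundary after position i
    if (length(new_val) == 0L) next
    pos_left <- cumsum(ys)[new_val]
    n_left <- new_val
    n_right <- n - n_left
    pos_right <- sum(ys) - pos_left
    p_l <- pos_left / n_left
    p_r <- pos_right / n_right
    gini <- (n_left * (2 * p_l * (1 - p_l)) +
             n_right * (2 * p_r * (1 - p_r))) / n
    thresholds <- (vs[new_val] + vs[new_val + 1L]) / 2
    i <- which.min(gini + thresholds * 0)   # first minimum = smallest threshold
    if (gini[i] < best_gini - 1e-12) {
      best_gini <- gini[i]
      best <- list(feature = j, threshold = thresholds[i], method = "impurity")
    }
  }
  best
}

new_leaf <- function(fraction, count) {
  list(type = "leaf", positive_fraction = fraction, estimation_count = count)
}

grow_node <- function(X, y, struct_idx, est_idx, config, depth, fallback) {
  est_frac <- if (length(est_idx) > 0L) mean(y[est_idx]) else fallback
  ys <- y[struct_idx]
  if (length(struct_idx) < config$min_split ||
      depth >= config$max_depth ||
      length(unique(ys)) == 1L) {
    return(new_leaf(est_frac, length(est_idx)))
  }
  candidates <- select_candidate_features(ncol(X), config$p1)
  split <- choose_split(X[struct_idx, , drop = FALSE], ys, candidates, config$p2)
  if (is.null(split)) {
    return(new_leaf(est_frac, length(est_idx)))
  }
  go_left_s <- X[struct_idx, split$feature] <= split$threshold
  go_left_e <- if (length(est_idx) > 0L) {
    X[est_idx, split$feature] <= split$threshold
  } else {
    logical(0)
  }
  if (all(go_left_s) || !any(go_left_s)) {
    # a random threshold can fail to separate structural samples
    return(new_leaf(est_frac, length(est_idx)))
  }
  child_fallback <- if (length(est_idx) > 0L) est_frac else fallback
  list(type = "split", feature = split$feature, threshold = split$threshold,
       left = grow_node(X, y, struct_idx[go_left_s], est_idx[go_left_e],
                        config, depth + 1L, child_fallback),
       right = grow_node(X, y, struct_idx[!go_left_s], est_idx[!go_left_e],
                         config, depth + 1L, child_fallback))
}

#' Grow a single BRF tree
#'
#' @param X Feature matrix.
#' @param y Binary labels (0/1).
#' @param struct_idx Structural sample indices (shape the tree).
#' @param est_idx Estimation sample indices (fill the leaves).
#' @param config A `brf_config`.
#' @return Tree root node (nested list; `type` `"split"` or `"leaf"`).
#' @export
grow_tree <- function(X, y, struct_idx, est_idx, config) {
  if (length(struct_idx) == 0L) {
    stop_mda("empty structural set", class = "mda_degenerate_error")
  }
  global_frac <- if (length(est_idx) > 0L) mean(y[est_idx]) else mean(y[struct_idx])
  grow_node(X, y, struct_idx, est_idx, config, 0L, global_frac)
}

#' Fit a Bernoulli Random Forest
#'
#' Each tree draws its own sample (bootstrap by default), its own
#' structural/estimation partition, and its own RNG stream derived from
#' `config$seed` and the tree index, so a fixed seed reproduces the forest
#' exactly.
#'
#' @param X Feature matrix (`n x D`), e.g. encoded pair features.
#' @param y Binary labels (0/1), both classes present.
#' @param config A `brf_config`.
#' @return A `brf_model`: list of tree roots plus `config` and
#'   `n_features`.
#' @export
brf_fit <- function(X, y, config = brf_config()) {
  X <- as.matrix(X)
  if (nrow(X) != length(y) || nrow(X) < 2L) {
    stop_mda("need |X| == |y| >= 2", class = "mda_config_error")
  }
  if (length(unique(y)) < 2L) {
    stop_mda("training labels contain a single class", class = "mda_training_error")
  }
  n <- nrow(X)
  trees <- vector("list", config$n_trees)
  for (t in seq_len(config$n_trees)) {
    tree_seed <- derive_seed(config$seed, "tree", t)
    trees[[t]] <- with_seed(tree_seed, {
      idx <- if (config$bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
      if (config$structural_fraction >= 1) {
        parts <- list(structural = idx, estimation = idx)
      } else {
        n_struct <- max(1L, min(length(idx) - 1L,
                                floor(config$structural_fraction * length(idx) + 0.5)))
        shuffled <- sample(idx)
        parts <- list(structural = shuffled[seq_len(n_struct)],
                      estimation = shuffled[(n_struct + 1L):length(idx)])
      }
      grow_tree(X, y, parts$structural, parts$estimation, config)
    })
  }
  structure(list(trees = trees, config = config, n_features = ncol(X)),
            class = "brf_model")
}

#' @export
print.brf_model <- function(x, ...) {
  cat(sprintf("<brf_model: %d trees, %d features, p1=%.3g, p2=%.3g>\n",
              length(x$trees), x$n_features, x$config$p1, x$config$p2))
  invisible(x)
}

# Vectorized routing of all rows of X through one tree.
route_tree <- function(node, X, idx, out) {
  if (node$type == "leaf") {
    out[idx] <- node$positive_fraction
    return(out)
  }
  go_left <- X[idx, node$feature] <= node$threshold
  if (any(go_left)) out <- route_tree(node$left, X, idx[go_left], out)
  if (any(!go_left)) out <- route_tree(node$right, X, idx[!go_left], out)
  out
}

#' Score samples with a BRF model
#'
#' The score of a sample is the mean over trees of the positive fraction
#' of the leaf it routes to.
#'
#' @param model A `brf_model`.
#' @param X Feature matrix with `model$n_features` columns.
#' @return Numeric scores in `[0, 1]`.
#' @export
brf_predict <- function(model, X) {
  stopifnot(inherits(model, "brf_model"))
  X <- as.matrix(X)
  if (ncol(X) != model$n_features) {
    stop_mda("X has %d columns, model expects %d", ncol(X), model$n_features,
             class = "mda_shape_error")
  }
  n <- nrow(X)
  total <- numeric(n)
  for (tree in model$trees) {
    total <- total + route_tree(tree, X, seq_len(n), numeric(n))
  }
  total / length(model$trees)
}

#' Structure-only hash of a tree
#'
#' Serializes split features and thresholds (not leaf fractions), so two
#' trees with identical shape but different estimation data hash equal.
#'
#' @param node Tree root.
#' @return Character digest.
#' @export
tree_structure_hash <- function(node) {
  ser <- function(nd) {
    if (nd$type == "leaf") return("L")
    sprintf("(%d:%.12g|%s|%s)", nd$feature, nd$threshold,
            ser(nd$left), ser(nd$right))
  }
  ser(node)
}
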