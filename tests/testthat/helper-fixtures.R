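# Shared fixtures and independent brute-force oracles. Oracles deliberately
# use naive enumeration so they share no code path with the package.

# Small planted-structure study used by unit tests (fast to cross-validate).
tiny_synth <- function(seed = 5L) {
  generate_synthetic(synthetic_spec(
    nd = 30L, nm = 12L, n_blocks = 3L,
    assoc_density_in = 0.5, assoc_density_out = 0.02,
    sim_noise = 0.05, n_side_effect_terms = 30L, seed = seed))
}

tiny_sims <- function(synth) {
  build_similarities(synth$dataset, synth$structure_sim, synth$profiles,
                     synth$microbe_sim)
}

# Light pipeline settings for unit tests.
tiny_cv_config <- function(master_seed = 3L, sampler = "random", ...) {
  cv_config(n_folds = 5L, n_repeats = 1L, sampler = sampler,
            encoder = list(epochs = 6L, batch_size = 16L),
            brf = brf_config(n_trees = 25L, min_split = 5L),
            master_seed = master_seed, ...)
}

# --- oracles -----------------------------------------------------------------

# Jaccard by direct set enumeration.
oracle_jaccard <- function(set_i, set_j) {
  u <- length(union(set_i, set_j))
  if (u == 0) return(0)
  length(intersect(set_i, set_j)) / u
}

# AUC by counting all positive/negative comparisons, ties worth 1/2.
oracle_auc <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (q in neg) {
    wins <- wins + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  wins / (length(pos) * length(neg))
}

# Precision/recall by explicit threshold sweep.
oracle_pr <- function(pos, neg) {
  th <- sort(unique(c(pos, neg)), decreasing = TRUE)
  do.call(rbind, lapply(th, function(t) {
    tp <- sum(pos >= t); fp <- sum(neg >= t)
    data.frame(threshold = t, recall = tp / length(pos),
               precision = tp / (tp + fp))
  }))
}

# Neighbour counts by double loop.
oracle_density <- function(X, radius) {
  n <- nrow(X)
  sapply(seq_len(n), function(i) {
    sum(sqrt(colSums((t(X) - X[i, ])^2)) <= radius + 1e-12) - 1L
  })
}

# Reference CART-style tree for the BRF degenerate limit (p1 = p2 = 0,
# structural = estimation = full sample). Consumes the RNG exactly as the
# BRF grower does (one uniform for B1, the candidate draw, one uniform for
# B2 whenever a non-constant candidate exists), but the split search and
# routing logic are written independently: per-candidate exhaustive scan
# over midpoints, weighted Gini computed from explicit left/right counts.
oracle_cart_node <- function(X, y, idx, min_split, max_depth, depth) {
  leaf <- function() list(type = "leaf", positive_fraction = mean(y[idx]),
                          estimation_count = length(idx))
  if (length(idx) < min_split || depth >= max_depth ||
      length(unique(y[idx])) == 1L) {
    return(leaf())
  }
  D <- ncol(X)
  stats::runif(1)                                   # B1 draw (p1 = 0)
  cand <- sort(sample.int(D, min(ceiling(sqrt(D)), D)))
  varying <- cand[sapply(cand, function(j) {
    v <- X[idx, j]; max(v) > min(v)
  })]
  if (length(varying) == 0L) return(leaf())
  stats::runif(1)                                   # B2 draw (p2 = 0)
  best <- NULL
  for (j in sort(varying)) {
    vals <- sort(unique(X[idx, j]))
    if (length(vals) < 2L) next
    for (i in seq_len(length(vals) - 1L)) {
      thr <- (vals[i] + vals[i + 1L]) / 2
      left <- idx[X[idx, j] <= thr]
      right <- idx[X[idx, j] > thr]
      gini_part <- function(ids) {
        f <- mean(y[ids]); length(ids) * 2 * f * (1 - f)
      }
      g <- (gini_part(left) + gini_part(right)) / length(idx)
      if (is.null(best) || g < best$g - 1e-12) {
        best <- list(j = j, thr = thr, g = g)
      }
    }
  }
  left_idx <- idx[X[idx, best$j] <= best$thr]
  right_idx <- idx[X[idx, best$j] > best$thr]
  list(type = "split", feature = best$j, threshold = best$thr,
       left = oracle_cart_node(X, y, left_idx, min_split, max_depth, depth + 1L),
       right = oracle_cart_node(X, y, right_idx, min_split, max_depth, depth + 1L))
}

oracle_cart_tree <- function(X, y, seed, min_split = 10L, max_depth = 25L) {
  tree_seed <- derive_seed(seed, "tree", 1L)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(tree_seed)
  oracle_cart_node(X, y, seq_len(nrow(X)), min_split, max_depth, 0L)
}

# Score a sample through an oracle tree.
oracle_route <- function(node, x) {
  while (node$type == "split") {
    node <- if (x[node$feature] <= node$threshold) node$left else node$right
  }
  node$positive_fraction
}
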