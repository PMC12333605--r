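# Seeded synthetic data with planted block structure.
#
# Drugs and microbes are partitioned into matching blocks; a drug tends to
# associate with microbes of its own block, and entities of the same block
# are similar. This is exactly the statistical premise the predictor
# exploits (similar drugs/microbes share associations), so the pipeline's
# cross-validated AUC on this data measures whether each stage preserves
# the planted signal.

#' Synthetic study specification
#'
#' Defaults define the package's reference synthetic condition: 120 drugs
#' x 40 microbes in 4 blocks, within-block association probability 0.3
#' against a 0.01 background, similarity noise 0.05, a 60-term side-effect
#' vocabulary.
#'
#' @param nd,nm Numbers of drugs and microbes.
#' @param n_blocks Planted co-association clusters.
#' @param assoc_density_in Within-block association probability.
#' @param assoc_density_out Background association probability
#'   (must be `< assoc_density_in`).
#' @param sim_noise Half-width of the symmetric uniform noise added to
#'   similarities.
#' @param n_side_effect_terms Side-effect vocabulary size.
#' @param seed Integer seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(nd = 120L, nm = 40L, n_blocks = 4L,
                           assoc_density_in = 0.3, assoc_density_out = 0.01,
                           sim_noise = 0.05, n_side_effect_terms = 60L,
                           seed = 7L) {
  if (!(assoc_density_out >= 0 && assoc_density_out < assoc_density_in &&
        assoc_density_in <= 1)) {
    stop_mda("need 0 <= assoc_density_out < assoc_density_in <= 1",
             class = "mda_config_error")
  }
  if (n_blocks < 1L || nd < n_blocks || nm < n_blocks) {
    stop_mda("need nd, nm >= n_blocks >= 1", class = "mda_config_error")
  }
  if (sim_noise < 0) {
    stop_mda("sim_noise must be >= 0", class = "mda_config_error")
  }
  structure(list(nd = as.integer(nd), nm = as.integer(nm),
                 n_blocks = as.integer(n_blocks),
                 assoc_density_in = assoc_density_in,
                 assoc_density_out = assoc_density_out,
                 sim_noise = sim_noise,
                 n_side_effect_terms = as.integer(n_side_effect_terms),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

block_assign <- function(n, n_blocks) {
  sort(rep_len(seq_len(n_blocks), n))
}

# Block-structured similarity: within-block 0.8, cross-block 0.1, plus
# symmetric uniform noise, clipped to [0, 1], diagonal 1.
block_similarity <- function(blocks, noise, ids) {
  n <- length(blocks)
  S <- ifelse(outer(blocks, blocks, `==`), 0.8, 0.1)
  if (noise > 0) {
    eps <- matrix(stats::runif(n * n, -noise, noise), n, n)
    eps <- (eps + t(eps)) / 2
    S <- S + eps
  }
  S[S < 0] <- 0
  S[S > 1] <- 1
  diag(S) <- 1
  new_similarity_matrix(entity_catalog(ids), S)
}

#' Generate a synthetic study
#'
#' Produces all four inputs the pipeline consumes: a binary association
#' dataset, a raw drug structure similarity matrix, drug side-effect
#' profiles, and a microbe sequence similarity matrix, all reproducible
#' from `spec$seed`.
#'
#' Associations are Bernoulli draws: probability `assoc_density_in` when
#' the drug's and microbe's blocks match, `assoc_density_out` otherwise.
#' Similarities are 0.8 within block / 0.1 across, plus symmetric uniform
#' noise of half-width `sim_noise`, clipped to `[0, 1]` with unit
#' diagonal. Side-effect profiles combine a per-block core term set (drawn
#' with probability 0.8 per drug) with rarer private terms, so Jaccard
#' similarity tracks block membership.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `dataset` (association_dataset), `structure_sim`
#'   (similarity_matrix), `profiles` (side_effect_profiles), `microbe_sim`
#'   (similarity_matrix), and the block assignments `drug_blocks`,
#'   `microbe_blocks`.
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    drug_ids <- sprintf("drug_%03d", seq_len(spec$nd))
    microbe_ids <- sprintf("microbe_%03d", seq_len(spec$nm))
    db <- block_assign(spec$nd, spec$n_blocks)
    mb <- block_assign(spec$nm, spec$n_blocks)

    p <- ifelse(outer(db, mb, `==`), spec$assoc_density_in,
                spec$assoc_density_out)
    A <- matrix(as.numeric(stats::runif(length(p)) < p), spec$nd, spec$nm)
    # every CV fold needs positives; re-seed empty datasets deterministically
    if (sum(A) == 0) {
      A[cbind(seq_len(spec$n_blocks),
              match(seq_len(spec$n_blocks), mb))] <- 1
    }
    dataset <- new_association_dataset(entity_catalog(drug_ids),
                                       entity_catalog(microbe_ids), A)

    structure_sim <- block_similarity(db, spec$sim_noise, drug_ids)
    microbe_sim <- block_similarity(mb, spec$sim_noise, microbe_ids)

    # side-effect vocabulary: a core set per block + shared private tail
    n_terms <- spec$n_side_effect_terms
    core_size <- max(1L, n_terms %/% (2L * spec$n_blocks))
    core_of <- split(seq_len(core_size * spec$n_blocks),
                     rep(seq_len(spec$n_blocks), each = core_size))
    private_pool <- setdiff(seq_len(n_terms), unlist(core_of))
    terms <- sprintf("se_%03d", seq_len(n_terms))
    profiles <- lapply(seq_len(spec$nd), function(i) {
      core <- core_of[[db[i]]]
      keep <- core[stats::runif(length(core)) < 0.8]
      priv <- if (length(private_pool) > 0L) {
        private_pool[stats::runif(length(private_pool)) < 0.1]
      } else {
        integer(0)
      }
      terms[sort(unique(c(keep, priv)))]
    })
    names(profiles) <- drug_ids
    profiles <- profiles[lengths(profiles) > 0L]

    list(dataset = dataset, structure_sim = structure_sim,
         profiles = side_effect_profiles(profiles),
         microbe_sim = microbe_sim, drug_blocks = db, microbe_blocks = mb)
  })
}

#' Shuffle associations (signal destruction control)
#'
#' Keeps the number of known associations but places them uniformly at
#' random, breaking the link between similarity blocks and associations;
#' the pipeline's AUC on the shuffled data should be near 0.5.
#'
#' @param dataset An `association_dataset`.
#' @param seed Integer seed.
#' @return A new `association_dataset` with the same margins of ones.
#' @export
shuffle_associations <- function(dataset, seed) {
  n_ones <- sum(dataset$A)
  A <- matrix(0, nrow(dataset$A), ncol(dataset$A))
  pos <- with_seed(seed, sample.int(length(A), n_ones))
  A[pos] <- 1
  new_association_dataset(dataset$drugs, dataset$microbes, A)
}

#' Fixed 4-drug x 3-microbe worked example
#'
#' A hard-coded miniature whose intermediate quantities (side-effect
#' Jaccard values, integrated similarity, pair vectors) are simple
#' fractions, used for step-by-step assertions.
#'
#' Side-effect sets: d1 = \{a, b\}, d2 = \{b, c\}, d3 = \{a, b, c\},
#' d4 = none. So e.g. Jaccard(d1, d2) = 1/3 and Jaccard(d1, d3) = 2/3.
#'
#' @return Same shape as [generate_synthetic()], without block fields.
#' @export
generate_worked_micro <- function() {
  drugs <- entity_catalog(c("d1", "d2", "d3", "d4"))
  microbes <- entity_catalog(c("m1", "m2", "m3"))
  A <- matrix(c(1, 0, 0,
                1, 1, 0,
                0, 0, 1,
                0, 0, 0), 4, 3, byrow = TRUE)
  dataset <- new_association_dataset(drugs, microbes, A)
  SS2 <- matrix(c(1.0, 0.6, 0.0, 0.2,
                  0.6, 1.0, 0.8, 0.0,
                  0.0, 0.8, 1.0, 0.4,
                  0.2, 0.0, 0.4, 1.0), 4, 4, byrow = TRUE)
  MV <- matrix(c(1.0, 0.5, 0.1,
                 0.5, 1.0, 0.3,
                 0.1, 0.3, 1.0), 3, 3, byrow = TRUE)
  profiles <- side_effect_profiles(list(
    d1 = c("a", "b"), d2 = c("b", "c"), d3 = c("a", "b", "c")
  ))
  list(dataset = dataset,
       structure_sim = new_similarity_matrix(drugs, SS2),
       profiles = profiles,
       microbe_sim = new_similarity_matrix(microbes, MV))
}

#' Write a synthetic study to disk
#'
#' Emits the same TSV/CSV formats the loaders read: `associations.tsv`,
#' `structure_sim.csv`, `side_effects.tsv`, `microbe_sim.csv`.
#'
#' @param synth Output of [generate_synthetic()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_synthetic <- function(synth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  save_dataset(synth$dataset, file.path(dir, "associations.tsv"))
  save_matrix(synth$structure_sim, file.path(dir, "structure_sim.csv"))
  save_side_effects(synth$profiles, file.path(dir, "side_effects.tsv"))
  save_matrix(synth$microbe_sim, file.path(dir, "microbe_sim.csv"))
  invisible(dir)
}
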