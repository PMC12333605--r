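# Run-configuration handling and the end-to-end pipeline entry point used
# by the command-line wrapper (inst/cli/mdapredict.R).

run_config_defaults <- function() {
  list(
    associations = NULL, structure_sim = NULL, side_effects = NULL,
    microbe_sim = NULL, out = NULL,
    cutoff = 0.5, integration_mode = "literal",
    sampler = "random",
    encoder = list(epochs = 20L, batch_size = 32L, learning_rate = 1e-3,
                   dropout_rate = 0.5),
    brf = list(n_trees = 100L, p1 = 0.05, p2 = 0.05, min_split = 10L,
               max_depth = 25L, bootstrap = TRUE, structural_fraction = 0.5),
    cv = list(enabled = FALSE, n_folds = 5L, n_repeats = 10L),
    rank = list(drug = NULL, k = 50L, mask = FALSE),
    seed = 1L, force = FALSE
  )
}

#' Read a run configuration file
#'
#' YAML file with the keys of the default configuration (inputs, `out`,
#' `cutoff`, `sampler`, `encoder`, `brf`, `cv`, `rank`, `seed`). Unknown
#' keys are rejected.
#'
#' @param path Path to a YAML file.
#' @return A `run_config` list (defaults filled in).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  defaults <- run_config_defaults()
  check_keys <- function(given, allowed, where) {
    unknown <- setdiff(names(given), allowed)
    if (length(unknown) > 0L) {
      stop_mda("unknown config key%s in %s: %s",
               if (length(unknown) > 1) "s" else "", where,
               paste(unknown, collapse = ", "), class = "mda_config_error")
    }
  }
  check_keys(raw, names(defaults), "run config")
  for (section in c("encoder", "brf", "cv", "rank")) {
    if (!is.null(raw[[section]])) {
      check_keys(raw[[section]], names(defaults[[section]]), section)
    }
  }
  cfg <- utils::modifyList(defaults, raw)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full pipeline from a configuration
#'
#' Executes the three stages in order -- integrated-similarity
#' construction, encoder training on the balanced pair sample, BRF fitting
#' on the encoded pairs -- then optionally repeated cross-validation
#' and/or per-drug ranking. Writes `summary.json`, the resolved
#' configuration (`run_config.yaml`), and stage outputs under
#' `config$out`.
#'
#' @param config A `run_config` (from [read_run_config()] or a compatible
#'   list).
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(config) {
  defaults <- run_config_defaults()
  config <- utils::modifyList(defaults, unclass(config))
  out <- config$out
  if (is.null(out)) {
    stop_mda("config$out is required", class = "mda_config_error")
  }
  if (dir.exists(out) && length(list.files(out)) > 0 && !isTRUE(config$force)) {
    stop_mda("output directory %s is non-empty; use force", out,
             class = "mda_io_error")
  }
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  for (key in c("associations", "structure_sim", "side_effects", "microbe_sim")) {
    if (is.null(config[[key]]) || !file.exists(config[[key]])) {
      stop_mda("input '%s' missing or not found: %s", key,
               config[[key]] %||% "<unset>", class = "mda_io_error")
    }
  }
  dataset <- load_association_table(config$associations)
  structure_sim <- load_similarity_matrix(config$structure_sim,
                                          expected = dataset$drugs)
  profiles <- load_side_effects(config$side_effects)
  microbe_sim <- load_similarity_matrix(config$microbe_sim,
                                        expected = dataset$microbes)
  sims <- build_similarities(dataset, structure_sim, profiles, microbe_sim,
                             cutoff = config$cutoff,
                             mode = config$integration_mode)
  save_matrix(new_similarity_matrix(dataset$drugs, sims$SD),
              file.path(out, "SD.csv"))
  save_matrix(new_similarity_matrix(dataset$microbes, sims$SM),
              file.path(out, "SM.csv"))

  summary <- list(
    n_drugs = length(dataset$drugs$ids),
    n_microbes = length(dataset$microbes$ids),
    n_associations = sum(dataset$A),
    feature_dim = length(dataset$drugs$ids) + length(dataset$microbes$ids),
    encoded_dim = (length(dataset$drugs$ids) + length(dataset$microbes$ids)) %/% 2L,
    sampler = config$sampler,
    seed = config$seed
  )

  brf_cfg <- do.call(brf_config, config$brf)

  if (isTRUE(config$cv$enabled)) {
    cvc <- cv_config(n_folds = config$cv$n_folds,
                     n_repeats = config$cv$n_repeats,
                     sampler = config$sampler,
                     encoder = config$encoder, brf = brf_cfg,
                     master_seed = derive_seed(config$seed, "cv"))
    cv <- cross_validate(dataset, sims, cvc, keep_curves = TRUE)
    utils::write.csv(data.frame(repeat_ = rep(seq_len(nrow(cv$fold_aucs)),
                                              each = ncol(cv$fold_aucs)),
                                fold = rep(seq_len(ncol(cv$fold_aucs)),
                                           nrow(cv$fold_aucs)),
                                auc = as.vector(t(cv$fold_aucs))),
                     file.path(out, "fold_aucs.csv"), row.names = FALSE)
    utils::write.csv(cv$roc[[1L]], file.path(out, "roc.csv"), row.names = FALSE)
    utils::write.csv(cv$pr[[1L]], file.path(out, "pr.csv"), row.names = FALSE)
    summary$cv <- list(mean_auc = cv$mean_auc, std_auc = cv$std_auc,
                       n_folds = cvc$n_folds, n_repeats = cvc$n_repeats)
  }

  if (!is.null(config$rank$drug)) {
    view <- if (isTRUE(config$rank$mask)) {
      mask_drug(dataset, config$rank$drug)
    } else {
      dataset
    }
    pipeline <- train_pipeline(view, sims, sampler = config$sampler,
                               encoder_args = config$encoder,
                               brf_cfg = brf_cfg,
                               seed = derive_seed(config$seed, "rank"))
    top <- rank_microbes_for_drug(pipeline, view, sims, config$rank$drug,
                                  k = config$rank$k)
    utils::write.csv(as.data.frame(top),
                     file.path(out, sprintf("top%d_%s.csv", config$rank$k,
                                            config$rank$drug)),
                     row.names = FALSE)
    summary$rank <- list(drug = config$rank$drug, k = nrow(top),
                         masked = isTRUE(config$rank$mask),
                         top_microbe = top$microbe[[1L]])
  }

  resolved <- config
  resolved$force <- NULL
  yaml::write_yaml(resolved, file.path(out, "run_config.yaml"))
  summary$package_version <- as.character(utils::packageVersion("mdapredict"))
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
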