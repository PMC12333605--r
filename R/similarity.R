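# Integrated similarity construction: side-effect Jaccard, chemical-structure
# cutoff, and the drug/microbe integration step.

#' Drug side-effect Jaccard similarity
#'
#' For drugs `i` and `j` with side-effect sets `N(i)` and `N(j)`, the
#' similarity is `|N(i) n N(j)| / |N(i) u N(j)|`. Pairs with no common side
#' effects (including pairs where either set is empty) score 0; the
#' diagonal is 1.
#'
#' @param profiles A `side_effect_profiles` object.
#' @param drugs An [entity_catalog()] of drugs (defines row/column order).
#' @return A `similarity_matrix` over `drugs`.
#' @export
jaccard_similarity <- function(profiles, drugs) {
  stopifnot(inherits(drugs, "entity_catalog"))
  keyed <- names(profiles)
  unknown <- setdiff(keyed, drugs$ids)
  if (length(unknown) > 0L) {
    stop_mda("side-effect profile for unknown drug(s): %s",
             paste(unknown, collapse = ", "), class = "mda_lookup_error")
  }
  nd <- length(drugs$ids)
  terms <- unique(unlist(unclass(profiles), use.names = FALSE))
  if (length(terms) == 0L) {
    return(new_similarity_matrix(drugs, diag(1, nd)))
  }
  # drug x term incidence; intersections and unions follow by matrix algebra
  M <- matrix(0, nd, length(terms))
  for (d in keyed) {
    M[drugs$index[[d]], match(profiles[[d]], terms)] <- 1
  }
  inter <- M %*% t(M)
  sizes <- rowSums(M)
  union <- outer(sizes, sizes, `+`) - inter
  S <- matrix(0, nd, nd)
  nz <- union > 0
  S[nz] <- inter[nz] / union[nz]
  new_similarity_matrix(drugs, S)
}

#' Apply the chemical-structure similarity cutoff
#'
#' Off-diagonal entries strictly below `cutoff` are set to 0; entries at or
#' above the cutoff are kept as-is (default) or set to 1
#' (`binarize = TRUE`). The diagonal is never modified.
#'
#' @param sim A `similarity_matrix` of raw structure-similarity scores.
#' @param cutoff Threshold in `[0, 1]` (default 0.5).
#' @param binarize If `TRUE`, surviving off-diagonal entries become 1.
#' @return A `similarity_matrix`.
#' @export
apply_structure_cutoff <- function(sim, cutoff = 0.5, binarize = FALSE) {
  stopifnot(inherits(sim, "similarity_matrix"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff < 0 || cutoff > 1) {
    stop_mda("cutoff must be a single value in [0, 1]", class = "mda_config_error")
  }
  S <- sim$S
  d <- diag(S)
  S[S < cutoff] <- 0
  if (binarize) S[S >= cutoff] <- 1
  diag(S) <- d
  new_similarity_matrix(sim$entities, S)
}

#' Integrate drug and microbe similarities
#'
#' The integrated drug similarity `SD` is the elementwise average of the
#' side-effect Jaccard matrix `SS1` and the cutoff-filtered structure
#' matrix `SS2`. The microbe similarity `SM` is the sequence-identity
#' matrix `MV`, used as-is. With `mode = "available"`, drug pairs where
#' either drug lacks side-effect data (per `se_available`) take `SD = SS2`
#' instead of `(0 + SS2) / 2`.
#'
#' @param ss1 Side-effect Jaccard `similarity_matrix` (drug catalog).
#' @param ss2 Structure `similarity_matrix` (same drug catalog).
#' @param mv Microbe sequence `similarity_matrix`.
#' @param mode `"literal"` (default): always average the two drug sources;
#'   `"available"`: average only over sources with data.
#' @param se_available Logical vector (one per drug) marking drugs with
#'   side-effect data; required for `mode = "available"`.
#' @return An `integrated_similarities` object with matrices `SD`
#'   (`nd x nd`) and `SM` (`nm x nm`) plus the two catalogs.
#' @export
integrate_similarities <- function(ss1, ss2, mv,
                                   mode = c("literal", "available"),
                                   se_available = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(ss1, "similarity_matrix"),
            inherits(ss2, "similarity_matrix"),
            inherits(mv, "similarity_matrix"))
  if (!identical(ss1$entities$ids, ss2$entities$ids)) {
    stop_mda("SS1 and SS2 drug catalogs differ", class = "mda_alignment_error")
  }
  SD <- (ss1$S + ss2$S) / 2
  if (mode == "available") {
    if (is.null(se_available) || length(se_available) != length(ss1$entities$ids)) {
      stop_mda("mode 'available' needs one se_available flag per drug",
               class = "mda_config_error")
    }
    no_se <- !(outer(se_available, se_available, `&`))
    SD[no_se] <- ss2$S[no_se]
  }
  diag(SD) <- 1
  structure(list(SD = SD, SM = mv$S,
                 drugs = ss1$entities, microbes = mv$entities),
            class = "integrated_similarities")
}

#' @export
print.integrated_similarities <- function(x, ...) {
  cat(sprintf("<integrated_similarities: SD %d x %d, SM %d x %d>\n",
              nrow(x$SD), ncol(x$SD), nrow(x$SM), ncol(x$SM)))
  invisible(x)
}

#' Build integrated similarities from raw inputs
#'
#' Convenience wrapper: Jaccard from profiles, cutoff on raw structure
#' scores, then integration.
#'
#' @param dataset An `association_dataset` (provides the catalogs).
#' @param structure_sim Raw structure `similarity_matrix` (drug catalog).
#' @param profiles A `side_effect_profiles` object.
#' @param microbe_sim Microbe sequence `similarity_matrix`.
#' @param cutoff Structure-similarity cutoff (default 0.5).
#' @param mode Integration mode, see [integrate_similarities()].
#' @return An `integrated_similarities` object.
#' @export
build_similarities <- function(dataset, structure_sim, profiles, microbe_sim,
                               cutoff = 0.5, mode = "literal") {
  ss1 <- jaccard_similarity(profiles, dataset$drugs)
  ss2 <- apply_structure_cutoff(structure_sim, cutoff)
  se_available <- dataset$drugs$ids %in% names(profiles)[lengths(unclass(profiles)) > 0]
  integrate_similarities(ss1, ss2, microbe_sim, mode = mode,
                         se_available = se_available)
}
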