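#' Endemism score of a category
#'
#' Fixed mapping (see [endemism_scores()]): exotic = -1, not endemic with
#' pantropical/neotropical distribution = 0, not endemic with South American
#' distribution = 1, regional endemic = 2, local endemic = 3. Unknown
#' categories raise a classification error; there is no silent default.
#'
#' @param category character vector of category names.
#' @return Integer score(s).
#' @export
score_species <- function(category) {
  scores <- endemism_scores()
  unknown <- setdiff(unique(category), names(scores))
  if (length(unknown)) {
    stop_betascape("betascape_classification_error",
                   "unknown endemism category: %s",
                   paste(unknown, collapse = ", "))
  }
  unname(scores[category])
}

#' Community-weighted mean (CWM) endemism of one community
#'
#' \eqn{\mathrm{CWM} = \sum_i n_i s_i / \sum_i n_i} over species with
#' abundance \eqn{n_i} and endemism score \eqn{s_i}; invariant to rescaling
#' all abundances, and bounded by the scores present.
#'
#' @param abundances named (or positionally matched) non-negative abundances.
#' @param scores per-species scores aligned with `abundances`; `NA` marks an
#'   unclassified species.
#' @param strict if `TRUE` (default) an unclassified species with positive
#'   abundance is an error; if `FALSE` such species are excluded from both
#'   numerator and denominator and their count is reported via
#'   `attr(, "n_excluded")`.
#' @return The CWM (numeric scalar).
#' @export
community_cwm <- function(abundances, scores, strict = TRUE) {
  if (length(abundances) != length(scores)) {
    stop_betascape("betascape_domain_error",
                   "abundances and scores must align")
  }
  pos <- abundances > 0
  missing_score <- pos & is.na(scores)
  if (any(missing_score)) {
    if (strict) {
      stop_betascape("betascape_classification_error",
                     "%d species with positive abundance lack an endemism score",
                     sum(missing_score))
    }
    pos <- pos & !is.na(scores)
  }
  if (sum(abundances[pos]) <= 0) {
    stop_betascape("betascape_domain_error", "community total abundance is zero")
  }
  out <- sum(abundances[pos] * scores[pos]) / sum(abundances[pos])
  attr(out, "n_excluded") <- sum(missing_score)
  out
}

#' Landscape endemism level
#'
#' Unweighted arithmetic mean of the member communities' CWM values.
#'
#' @param cwms numeric vector of community CWMs (>= 1 value).
#' @return The landscape mean CWM.
#' @export
landscape_endemism <- function(cwms) {
  if (length(cwms) < 1) {
    stop_betascape("betascape_design_error", "no community CWM values")
  }
  mean(cwms)
}

#' Per-community and per-landscape endemism tables for a study
#'
#' @param study a `synthetic_study`.
#' @param strict passed to [community_cwm()].
#' @return List with `communities` (inventory-level CWM) and `landscapes`
#'   (landscape-level mean CWM) data frames.
#' @export
endemism_table <- function(study, strict = TRUE) {
  scores <- study$species$score[match(colnames(study$abundances),
                                      study$species$species_id)]
  cwm <- vapply(seq_len(nrow(study$abundances)), function(i) {
    as.numeric(community_cwm(study$abundances[i, ], scores, strict = strict))
  }, numeric(1))
  communities <- data.frame(
    id = rownames(study$abundances),
    landscape_id = study$inventories$landscape_id[
      match(rownames(study$abundances), study$inventories$id)],
    cwm = cwm, stringsAsFactors = FALSE
  )
  landscapes <- aggregate(cwm ~ landscape_id, data = communities, FUN = mean)
  names(landscapes)[2] <- "endemism"
  list(communities = communities, landscapes = landscapes)
}
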