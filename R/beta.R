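#' Pairwise abundance-based Bray-Curtis dissimilarity and its partition
#'
#' With \eqn{A = \sum_i \min(x_i, y_i)}, \eqn{B = \sum_i (x_i - \min)} and
#' \eqn{C = \sum_i (y_i - \min)}: total dissimilarity
#' \eqn{d = (B + C) / (2A + B + C)}, balanced-variation component
#' \eqn{d_{bal} = \min(B, C) / (A + \min(B, C))} and abundance-gradient
#' component \eqn{d_{grad} = d - d_{bal}}.
#'
#' @param x,y non-negative count vectors of equal length, not both all-zero.
#' @return List: `d`, `d_balanced`, `d_gradient`, `A`, `B`, `C`.
#' @export
pairwise_bray <- function(x, y) {
  if (length(x) != length(y)) {
    stop_betascape("betascape_domain_error", "x and y must have equal length")
  }
  if (any(x < 0) || any(y < 0)) {
    stop_betascape("betascape_domain_error", "counts must be non-negative")
  }
  if (sum(x) == 0 && sum(y) == 0) {
    stop_betascape("betascape_domain_error", "both communities are empty")
  }
  m <- pmin(x, y)
  A <- sum(m)
  B <- sum(x) - A
  C <- sum(y) - A
  d <- (B + C) / (2 * A + B + C)
  d_bal <- min(B, C) / (A + min(B, C))
  if (!is.finite(d_bal)) d_bal <- 0       # x == y == m, B = C = 0
  list(d = d, d_balanced = d_bal, d_gradient = d - d_bal, A = A, B = B, C = C)
}

#' Abundance-based multiple-site Bray-Curtis partition
#'
#' Sums the pairwise quantities over all unordered site pairs
#' (\eqn{A_{jk}}, \eqn{b_{jk}}, \eqn{b_{kj}}):
#' total = \eqn{(\sum \min + \sum \max) / (2\sum A + \sum \min + \sum \max)},
#' balanced = \eqn{\sum \min / (\sum A + \sum \min)}, gradient = total -
#' balanced, where min/max are over \eqn{(b_{jk}, b_{kj})} per pair. For two
#' sites this reduces exactly to [pairwise_bray()].
#'
#' @param m abundance matrix (sites x species, >= 2 rows).
#' @return List: `beta_total`, `beta_balanced`, `beta_gradient`.
#' @export
multi_site_partition <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2) {
    stop_betascape("betascape_domain_error", "need at least 2 sites")
  }
  if (any(rowSums(m) == 0)) {
    stop_betascape("betascape_domain_error", "all-zero site row")
  }
  n <- nrow(m)
  sumA <- 0; sum_min <- 0; sum_max <- 0
  for (j in seq_len(n - 1)) {
    for (k in (j + 1):n) {
      mn <- pmin(m[j, ], m[k, ])
      A <- sum(mn)
      b_jk <- sum(m[j, ]) - A
      b_kj <- sum(m[k, ]) - A
      sumA <- sumA + A
      sum_min <- sum_min + min(b_jk, b_kj)
      sum_max <- sum_max + max(b_jk, b_kj)
    }
  }
  beta_total <- (sum_min + sum_max) / (2 * sumA + sum_min + sum_max)
  beta_balanced <- sum_min / (sumA + sum_min)
  list(beta_total = beta_total, beta_balanced = beta_balanced,
       beta_gradient = beta_total - beta_balanced)
}

#' Abundance-based Raup-Crick index for one community pair
#'
#' Null model preserving alpha diversity and total abundance: per replicate,
#' each null community draws its observed richness of species without
#' replacement with probability proportional to `pool_freq`, then distributes
#' its observed total abundance among them with probability proportional to
#' `pool_relabund`. The observed Bray-Curtis dissimilarity is compared to the
#' null distribution:
#' `rc_raw = 2 * ((#(d* < d_obs) + 0.5 * #(d* = d_obs)) / n_reps) - 1`,
#' which lies in `[-1, 1]` by construction (near -1: more similar than
#' chance; near +1: more dissimilar; near 0: indistinguishable from chance).
#'
#' @param x,y non-negative count vectors over the pool's species.
#' @param pool_freq per-species occurrence frequency (sampling weight for
#'   which species occur).
#' @param pool_relabund per-species relative abundance (weight for how
#'   individuals are distributed).
#' @param n_reps null replicates (default 999).
#' @param seed optional RNG seed.
#' @return `rc_raw` in `[-1, 1]`.
#' @export
raup_crick_pair <- function(x, y, pool_freq, pool_relabund, n_reps = 999,
                            seed = NULL) {
  S <- length(pool_freq)
  if (length(x) != S || length(y) != S || length(pool_relabund) != S) {
    stop_betascape("betascape_domain_error",
                   "x, y and pool vectors must share one species set")
  }
  if (any((x > 0 | y > 0) & pool_freq <= 0)) {
    stop_betascape("betascape_domain_error",
                   "pool is missing a species present in x or y")
  }
  rich_x <- sum(x > 0); rich_y <- sum(y > 0)
  if (rich_x < 1 || rich_y < 1) {
    stop_betascape("betascape_domain_error", "communities must be non-empty")
  }
  if (rich_x > sum(pool_freq > 0) || rich_y > sum(pool_freq > 0)) {
    stop_betascape("betascape_domain_error",
                   "observed richness exceeds the pool size")
  }
  if (!is.null(seed)) set.seed(seed)
  d_obs <- pairwise_bray(x, y)$d
  d_null <- rc_null_cpp(rich_x, as.integer(sum(x)), rich_y, as.integer(sum(y)),
                        as.numeric(pool_freq), as.numeric(pool_relabund),
                        as.integer(n_reps))
  eps <- 1e-12
  n_less <- sum(d_null < d_obs - eps)
  n_tie <- sum(abs(d_null - d_obs) <= eps)
  2 * ((n_less + 0.5 * n_tie) / n_reps) - 1
}

#' Per-pair Raup-Crick values for an abundance matrix (batched engine)
#'
#' Low-level access to the batched null-model engine: one null community per
#' inventory per replicate, all pairwise null dissimilarities of a replicate
#' sharing those draws (the matrix-per-permutation convention of null-model
#' dissimilarity tools). Uses the current R RNG state to seed its internal
#' stream, so results are reproducible under [set.seed()].
#'
#' @param m integer abundance matrix (rows = inventories).
#' @param pool_freq,pool_relabund pool weights over the matrix's columns.
#' @param n_reps null replicates.
#' @return Numeric vector of `rc_raw` per unordered row pair, in
#'   `(1,2), (1,3), ..., (n-1,n)` order.
#' @export
landscape_rc_pairs <- function(m, pool_freq, pool_relabund, n_reps = 999) {
  m <- as.matrix(m)
  storage.mode(m) <- "integer"
  landscape_rc_cpp(m, as.numeric(pool_freq), as.numeric(pool_relabund),
                   as.integer(n_reps))
}

#' Landscape-level beta diversity
#'
#' Computes the multi-site Bray-Curtis partition and the mean pairwise
#' Raup-Crick index over all unordered inventory pairs, with the null pool
#' built from the landscape's own inventories (occurrence frequency =
#' proportion of inventories holding the species; relative abundance = pooled
#' counts). `rc_rescaled = (rc_raw + 1) / 2` maps the index to `[0, 1]` for
#' comparability with total beta diversity.
#'
#' @param m abundance matrix (inventories x species, >= 2 rows).
#' @param n_reps null replicates per pair (default 999).
#' @param seed RNG seed for the null model.
#' @param pool optional externally supplied pool (list with `freq` and
#'   `relabund` over the matrix's species columns); default uses the
#'   landscape's own inventories.
#' @return List: `beta_total`, `beta_balanced`, `beta_gradient`, `rc_raw`,
#'   `rc_rescaled`, `n_null_reps`, `seed`.
#' @export
landscape_beta <- function(m, n_reps = 999, seed = 1L, pool = NULL) {
  m <- as.matrix(m)
  part <- multi_site_partition(m)
  if (is.null(pool)) {
    pool <- list(freq = colMeans(m > 0), relabund = colSums(m) / sum(m))
  }
  set.seed(seed)
  rc_vals <- landscape_rc_pairs(m, pool$freq, pool$relabund, n_reps)
  rc_raw <- mean(rc_vals)
  c(part, list(rc_raw = rc_raw, rc_rescaled = (rc_raw + 1) / 2,
               n_null_reps = n_reps, seed = seed))
}

#' Per-landscape beta-diversity table for a study
#'
#' @param study a `synthetic_study`.
#' @param n_reps null replicates per pair.
#' @param seed master seed; per-landscape seeds are derived by stable hashing
#'   of the landscape id.
#' @return Data frame with one row per landscape.
#' @export
beta_diversity_table <- function(study, n_reps = 999, seed = 1L) {
  ids <- study$truth$landscape_id
  rows <- lapply(ids, function(lid) {
    inv <- study$inventories$id[study$inventories$landscape_id == lid]
    m <- study$abundances[inv, , drop = FALSE]
    m <- m[, colSums(m) > 0, drop = FALSE]
    b <- landscape_beta(m, n_reps = n_reps,
                        seed = derive_seed(seed, paste0("beta:", lid)))
    data.frame(landscape_id = lid, beta_total = b$beta_total,
               beta_balanced = b$beta_balanced,
               beta_gradient = b$beta_gradient,
               rc_raw = b$rc_raw, rc_rescaled = b$rc_rescaled,
               n_null_reps = n_reps, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
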