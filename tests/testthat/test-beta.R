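# beta diversity: pairwise partition, multi-site partition, Raup-Crick nulls

test_that("pairwise Bray-Curtis partition matches hand evaluation", {
  pb <- pairwise_bray(c(3, 0, 1), c(1, 2, 1))
  expect_equal(pb$A, 2)
  expect_equal(pb$B, 2)
  expect_equal(pb$C, 2)
  expect_equal(pb$d, 0.5)
  expect_equal(pb$d_balanced, 0.5)
  expect_equal(pb$d_gradient, 0)

  same <- pairwise_bray(c(2, 5, 1), c(2, 5, 1))
  expect_equal(same$d, 0)

  grad <- pairwise_bray(c(2, 2), c(1, 1))
  expect_equal(grad$d, 1 / 3)
  expect_equal(grad$d_balanced, 0)
  expect_equal(grad$d_gradient, 1 / 3)

  expect_error(pairwise_bray(c(0, 0), c(0, 0)), class = "betascape_domain_error")
  expect_error(pairwise_bray(c(1, 2), c(1, 2, 3)), class = "betascape_domain_error")
})

test_that("pairwise d agrees with vegan's Bray-Curtis on random counts", {
  skip_if_not_installed("vegan")
  set.seed(12)
  for (i in 1:50) {
    m <- matrix(rpois(20, 3), nrow = 2)
    if (any(rowSums(m) == 0)) next
    expect_equal(pairwise_bray(m[1, ], m[2, ])$d,
                 as.numeric(vegan::vegdist(m, method = "bray")),
                 tolerance = 1e-12)
  }
})

test_that("multi-site partition reduces to the pairwise case and obeys additivity", {
  set.seed(20)
  m2 <- matrix(rpois(16, 4) + 1, nrow = 2)
  ms <- multi_site_partition(m2)
  pb <- pairwise_bray(m2[1, ], m2[2, ])
  expect_equal(ms$beta_total, pb$d, tolerance = 1e-14)
  expect_equal(ms$beta_balanced, pb$d_balanced, tolerance = 1e-14)

  ident <- matrix(rep(c(3, 1, 4), 3), nrow = 3, byrow = TRUE)
  msi <- multi_site_partition(ident)
  expect_equal(unlist(msi), c(beta_total = 0, beta_balanced = 0,
                              beta_gradient = 0))

  m3 <- rbind(c(3, 0, 1), c(1, 2, 1), c(2, 2, 0))
  ms3 <- multi_site_partition(m3)
  orc <- oracle_multi_site(m3)
  expect_equal(ms3$beta_total, unname(orc["total"]), tolerance = 1e-14)
  expect_equal(ms3$beta_balanced, unname(orc["balanced"]), tolerance = 1e-14)

  # additivity + scale and permutation invariance on random matrices
  for (i in 1:200) {
    n <- sample(2:6, 1)
    m <- matrix(rpois(n * 8, 2), nrow = n)
    m <- m[rowSums(m) > 0, , drop = FALSE]
    if (nrow(m) < 2) next
    ms <- multi_site_partition(m)
    expect_lt(abs(ms$beta_total - ms$beta_balanced - ms$beta_gradient), 1e-12)
    expect_equal(multi_site_partition(m * 7L)$beta_total, ms$beta_total,
                 tolerance = 1e-12)
    expect_equal(
      multi_site_partition(m[sample(nrow(m)), sample(ncol(m))])$beta_total,
      ms$beta_total, tolerance = 1e-12)
  }
})

test_that("Raup-Crick bounds, extremes and input checks", {
  set.seed(30)
  S <- 200
  pool_freq <- runif(S)
  pool_rel <- runif(S); pool_rel <- pool_rel / sum(pool_rel)

  # pool-saturated identical communities: observed d = 0 at or below all nulls
  x_full <- as.integer(round(pool_rel * 1e4)) + 1L
  rc_id <- raup_crick_pair(x_full, x_full, rep(1, S), pool_rel,
                           n_reps = 999, seed = 1)
  expect_lt(rc_id, -0.9)

  # species-disjoint communities of richness 10 from a 200-species pool,
  # with the landscape-own occurrence pool (freq > 0 only for observed
  # species): null draws overlap almost surely, observed d = 1 exceeds them
  x <- rep(0L, S); y <- rep(0L, S)
  x[1:10] <- 30L; y[11:20] <- 30L
  own_freq <- colMeans(rbind(x, y) > 0)
  own_rel <- (x + y) / sum(x + y)
  rc_dis <- raup_crick_pair(x, y, own_freq, own_rel, n_reps = 999, seed = 2)
  expect_gt(rc_dis, 0.9)
  expect_lte(rc_dis, 1)
  expect_gte(rc_id, -1)

  bad_pool <- pool_freq; bad_pool[1] <- 0
  expect_error(raup_crick_pair(x, y, bad_pool, pool_rel),
               class = "betascape_domain_error")
  expect_error(raup_crick_pair(rep(0L, S), y, pool_freq, pool_rel),
               class = "betascape_domain_error")
})

test_that("replicate counts converge and the two null engines agree", {
  set.seed(33)
  S <- 60
  freq <- runif(S); rel <- runif(S); rel <- rel / sum(rel)
  x <- rep(0L, S); x[sample(S, 25)] <- rpois(25, 8) + 1L
  y <- rep(0L, S); y[sample(S, 20)] <- rpois(20, 10) + 1L
  rc_999 <- raup_crick_pair(x, y, freq, rel, n_reps = 999, seed = 7)
  rc_9999 <- raup_crick_pair(x, y, freq, rel, n_reps = 9999, seed = 8)
  expect_lt(abs(rc_999 - rc_9999), 0.05)

  # per-pair engine (R RNG, Efraimidis keys + rmultinom) vs batched engine
  # (xoshiro + Fenwick + alias): same null model, two implementations
  set.seed(9)
  rc_batch <- mean(replicate(20, landscape_rc_pairs(rbind(x, y), freq, rel, 999)))
  set.seed(10)
  rc_pair <- mean(replicate(20, raup_crick_pair(x, y, freq, rel, n_reps = 999)))
  expect_lt(abs(rc_batch - rc_pair), 0.03)
})

test_that("landscape_beta aggregates pairs deterministically", {
  set.seed(40)
  m <- matrix(rpois(3 * 30, 2), nrow = 3)
  m <- m + (rowSums(m) == 0)           # guard all-zero rows
  b1 <- landscape_beta(m, n_reps = 199, seed = 5)
  b2 <- landscape_beta(m, n_reps = 199, seed = 5)
  expect_identical(b1, b2)
  expect_equal(b1$rc_rescaled, (b1$rc_raw + 1) / 2, tolerance = 1e-15)
  expect_lt(abs(b1$beta_total - b1$beta_balanced - b1$beta_gradient), 1e-12)

  # 2-row landscape: rc equals the single pair's value under the same stream
  m2 <- m[1:2, , drop = FALSE]
  b <- landscape_beta(m2, n_reps = 199, seed = 11)
  pool <- list(freq = colMeans(m2 > 0), relabund = colSums(m2) / sum(m2))
  set.seed(11)
  rc_pair <- landscape_rc_pairs(m2, pool$freq, pool$relabund, 199)
  expect_equal(b$rc_raw, rc_pair[1])
})

test_that("null-process communities give Raup-Crick centred near zero", {
  # The null regenerates communities at the *realized* richness, so observed
  # draws whose chosen species received zero individuals would shift the
  # centre; the fixture keeps structural zeros rare (even relative
  # abundances, generous totals) so the process is self-consistent.
  set.seed(50)
  S <- 100
  freq <- runif(S, 0.1, 1)
  rel <- runif(S, 0.5, 1.5); rel <- rel / sum(rel)
  draw_null <- function(rich, tot) {
    sp <- sample.int(S, rich, prob = freq)
    x <- rep(0L, S)
    x[sp] <- as.integer(rmultinom(1, tot, rel[sp]))
    x
  }
  rc <- replicate(500, {
    x <- draw_null(20, 250); y <- draw_null(25, 300)
    raup_crick_pair(x, y, freq, rel, n_reps = 199)
  })
  expect_lt(abs(mean(rc)), 0.1)
})

test_that("synthetic distance-decay studies yield mostly positive rescaled RC", {
  s <- generate_study(simulation_config(n_landscapes = 20, seed = 77))
  b <- beta_diversity_table(s, n_reps = 199, seed = 9)
  expect_gt(mean(b$rc_rescaled > 0.5), 0.5)
  expect_true(all(b$rc_rescaled >= 0 & b$rc_rescaled <= 1))
})
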