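# synthetic-data generator: rasters, species pools, communities, full studies

test_that("habitat raster growth controls cover exactly and is seed-reproducible", {
  # saturation / empty corner cases
  full <- generate_habitat_raster(9, 30, target_cover = 1, n_nuclei = 3, seed = 1)
  expect_true(all(full$values == 1L))
  empty <- generate_habitat_raster(9, 30, target_cover = 0, n_nuclei = 3, seed = 1)
  expect_identical(sum(empty$values), 0L)

  # 100x100 grid (9 km2 at 30 m), cover 0.3: exactly 3000 habitat cells
  r1 <- generate_habitat_raster(9, 30, target_cover = 0.3, n_nuclei = 5, seed = 42)
  expect_identical(dim(r1$values), c(100L, 100L))
  expect_identical(sum(r1$values == 1L), 3000L)
  r2 <- generate_habitat_raster(9, 30, target_cover = 0.3, n_nuclei = 5, seed = 42)
  expect_identical(r1$values, r2$values)

  # cover control invariant across a gradient
  for (tc in c(0.07, 0.33, 0.61, 0.94)) {
    r <- generate_habitat_raster(9, 30, target_cover = tc, n_nuclei = 4,
                                 seed = 100 + round(100 * tc))
    expect_lte(abs(mean(r$values == 1L) - tc), 1 / length(r$values))
  }

  expect_error(generate_habitat_raster(9, 30, target_cover = 1.2, n_nuclei = 1),
               class = "betascape_domain_error")
  expect_error(generate_habitat_raster(0.01, 30, target_cover = 0.5, n_nuclei = 1),
               class = "betascape_config_error")
})

test_that("nuclei count controls measured fragmentation at fixed cover", {
  set.seed(7)
  nuclei <- sample(1:50, 60, replace = TRUE)
  n_patches <- vapply(seq_along(nuclei), function(i) {
    r <- generate_habitat_raster(9, 30, target_cover = 0.3,
                                 n_nuclei = nuclei[i], seed = 500 + i)
    patches(r)$n_patches
  }, numeric(1))
  expect_gt(cor(nuclei, n_patches, method = "spearman"), 0.5)
})

test_that("species pool respects the endemism mix", {
  all_local <- generate_species_pool(20, c(0, 0, 0, 0, 1), seed = 1)
  expect_true(all(all_local$category == "local_endemic"))
  expect_true(all(all_local$score == 3L))

  all_exotic <- generate_species_pool(20, c(1, 0, 0, 0, 0), seed = 1)
  expect_true(all(all_exotic$score == -1L))

  p1 <- generate_species_pool(5, rep(0.2, 5), seed = 9)
  p2 <- generate_species_pool(5, rep(0.2, 5), seed = 9)
  expect_identical(p1, p2)
  expect_identical(nrow(p1), 5L)

  # frequencies converge to the mix for a large pool
  mix <- c(0.05, 0.4, 0.25, 0.2, 0.1)
  big <- generate_species_pool(20000, mix, seed = 3)
  freq <- table(factor(big$category, levels = names(endemism_scores()))) / 20000
  expect_lt(max(abs(as.numeric(freq) - mix)), 0.02)

  expect_error(generate_species_pool(10, c(0.5, 0.5, 0.5, 0, 0)),
               class = "betascape_domain_error")
  expect_error(generate_species_pool(3, rep(0.2, 5)),
               class = "betascape_config_error")
})

test_that("communities show no distance decay when the decay rate is zero", {
  cfg <- simulation_config(distance_decay_rate = 0,
                           homogenization_strength = 0,
                           cover_homogenization = 0,
                           endemism_cover_coupling = 0)
  pool <- generate_species_pool(cfg$pool_size, cfg$endemism_mix, seed = 2)
  set.seed(11)
  d_geo <- numeric(200); d_bc <- numeric(200)
  for (i in 1:200) {
    sites <- cbind(runif(2, 0, 10), runif(2, 0, 10))
    m <- generate_communities(sites, cover = 0.5, fragmentation = 0.5,
                              pool = pool, config = cfg)
    d_geo[i] <- sqrt(sum((sites[1, ] - sites[2, ])^2))
    d_bc[i] <- pairwise_bray(m[1, ], m[2, ])$d
  }
  fit <- summary(lm(d_bc ~ d_geo))
  expect_gt(fit$coefficients["d_geo", "Pr(>|t|)"], 0.01)
})

test_that("coincident sites sit at the sampling-noise floor (replicate-draw oracle)", {
  cfg <- simulation_config(homogenization_strength = 0,
                           cover_homogenization = 0,
                           endemism_cover_coupling = 0)
  pool <- generate_species_pool(cfg$pool_size, cfg$endemism_mix, seed = 2)
  set.seed(21)
  d_gen <- replicate(150, {
    sites <- matrix(rep(runif(2, 0, 10), each = 2), nrow = 2)
    m <- generate_communities(sites, cover = 0.5, fragmentation = 0.5,
                              pool = pool, config = cfg)
    pairwise_bray(m[1, ], m[2, ])$d
  })
  # oracle: same weight model written out directly (geometric profile, one
  # shared random-phase field value per species, independent site noise)
  S <- cfg$pool_size
  q <- betascape:::solve_geometric_q(S, cfg$alpha_mean,
                                     cfg$individuals_per_inventory)
  sigma <- betascape:::.betascape_sigma_field
  tau <- betascape:::.betascape_tau_site
  d_oracle <- replicate(150, {
    base <- (seq_len(S) - 1) * log(q) +
      sigma * sqrt(2) * cos(runif(S, 0, 2 * pi))
    w <- exp(rbind(base + rnorm(S, sd = tau), base + rnorm(S, sd = tau)))
    x <- rmultinom(1, cfg$individuals_per_inventory, w[1, ])
    y <- rmultinom(1, cfg$individuals_per_inventory, w[2, ])
    pairwise_bray(x, y)$d
  })
  expect_lt(abs(mean(d_gen) - mean(d_oracle)), 0.03)
})

test_that("endemism-cover coupling raises CWM endemism with cover", {
  cfg <- simulation_config(endemism_cover_coupling = 1)
  pool <- generate_species_pool(cfg$pool_size, cfg$endemism_mix, seed = 5)
  scores <- pool$score
  set.seed(31)
  cwm_at <- function(cover) {
    mean(replicate(100, {
      sites <- cbind(runif(2, 0, 10), runif(2, 0, 10))
      m <- generate_communities(sites, cover = cover, fragmentation = 0.5,
                                pool = pool, config = cfg)
      mean(apply(m, 1, function(row) sum(row * scores) / sum(row)))
    }))
  }
  expect_lt(cwm_at(0.1), cwm_at(0.9))
})

test_that("generate_study satisfies its structural contract", {
  cfg <- simulation_config(n_landscapes = 95, habitat_amount_range = c(0, 1),
                           seed = 4)
  s <- generate_study(cfg)
  counts <- table(s$inventories$landscape_id)
  expect_identical(length(counts), 95L)
  expect_true(all(counts >= 2 & counts <= 12))
  expect_gte(nrow(s$inventories), 190)
  expect_lte(nrow(s$inventories), 1140)
  expect_lt(min(s$truth$realized_cover), 0.05)
  expect_gt(max(s$truth$realized_cover), 0.95)
  expect_setequal(names(s$rasters), s$truth$landscape_id)
  expect_false(any(rowSums(s$abundances) == 0))
  # determinism contract: identical config twice gives identical tables
  s2 <- generate_study(simulation_config(n_landscapes = 95,
                                         habitat_amount_range = c(0, 1),
                                         seed = 4))
  expect_identical(s$inventories, s2$inventories)
  expect_identical(s$abundances, s2$abundances)
  expect_identical(s$truth, s2$truth)
  expect_identical(s$rasters, s2$rasters)
})

test_that("homogenization lowers beta diversity in high-patch-count landscapes", {
  # fragmentation per se is subdivision at *fixed* habitat amount, so the
  # tercile contrast is run on a fixed-cover gradient (otherwise the
  # patch-count/cover percolation coupling confounds the comparison)
  s <- generate_study(simulation_config(n_landscapes = 66, seed = 13,
                                        habitat_amount_range = c(0.5, 0.5)))
  ids <- s$truth$landscape_id
  bt <- vapply(ids, function(lid) {
    inv <- s$inventories$id[s$inventories$landscape_id == lid]
    m <- s$abundances[inv, , drop = FALSE]
    multi_site_partition(m[, colSums(m) > 0, drop = FALSE])$beta_total
  }, numeric(1))
  np <- vapply(ids, function(lid) patches(s$rasters[[lid]])$n_patches, numeric(1))
  terc <- quantile(np, c(1 / 3, 2 / 3))
  expect_lt(mean(bt[np >= terc[2]]), mean(bt[np <= terc[1]]))
})

test_that("studies round-trip through the plain-text study format", {
  dir <- withr::local_tempdir()
  s <- generate_study(simulation_config(n_landscapes = 4, seed = 8))
  write_study(s, dir)
  s2 <- read_study(dir)
  expect_equal(s2$inventories$id, s$inventories$id)
  expect_equal(s2$abundances, s$abundances)
  expect_equal(s2$truth$target_cover, s$truth$target_cover, tolerance = 1e-12)
  lid <- s$truth$landscape_id[1]
  expect_identical(s2$rasters[[lid]]$values, s$rasters[[lid]]$values)
  expect_identical(s2$rasters[[lid]]$year, s$rasters[[lid]]$year)
  expect_equal(s2$grid$extent, s$grid$extent, tolerance = 1e-9)
})
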