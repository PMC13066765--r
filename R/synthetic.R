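#' Configuration for a synthetic landscape study
#'
#' Bundles every knob of the synthetic-data generator: the landscape grid, the
#' habitat rasters (amount and fragmentation), the species pool, and the
#' community-assembly model (distance decay, fragmentation- and cover-driven
#' homogenization, endemism-cover coupling). Defaults emulate the structure of
#' a multi-landscape Atlantic Forest tree-inventory study: 95 landscapes of
#' 100 km2 at 30-m raster resolution, 2-12 inventories per landscape, and a
#' near-complete 0-100% habitat-cover gradient.
#'
#' @param n_landscapes number of landscapes.
#' @param landscape_area landscape area in km2.
#' @param cell_size raster cell size in metres.
#' @param habitat_amount_range length-2 fraction range of target habitat cover.
#' @param fragmentation_nuclei_range length-2 integer range of growth nuclei
#'   (controls expected patch count at fixed habitat amount).
#' @param inventories_per_landscape_range length-2 integer range (low >= 2).
#' @param pool_size species-pool size (>= 5).
#' @param endemism_mix length-5 probability vector over the endemism
#'   categories (exotic, pantropical/neotropical, South American, regional
#'   endemic, local endemic); must sum to 1.
#' @param distance_decay_rate per-km rate at which the spatial suitability
#'   field decorrelates; 0 switches distance decay off.
#' @param homogenization_strength dimensionless coefficient linking the nuclei
#'   count (fragmentation) to generalist dominance, hence to lower beta
#'   diversity.
#' @param cover_homogenization dimensionless coefficient linking habitat
#'   amount to generalist dominance (the generating negative cover effect on
#'   beta diversity).
#' @param endemism_cover_coupling dimensionless coefficient multiplying
#'   endemic-species weights by `1 + coupling * cover`.
#' @param alpha_mean expected species per inventory (calibrates the evenness
#'   of the geometric-series pool profile).
#' @param individuals_per_inventory individuals drawn per inventory.
#' @param seed master RNG seed.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_landscapes = 95,
                              landscape_area = 100,
                              cell_size = 30,
                              habitat_amount_range = c(0.02, 0.98),
                              fragmentation_nuclei_range = c(1L, 60L),
                              inventories_per_landscape_range = c(2L, 12L),
                              pool_size = 400,
                              endemism_mix = c(exotic = 0.03,
                                               not_endemic_pantropical_neotropical = 0.37,
                                               not_endemic_south_american = 0.25,
                                               regional_endemic = 0.20,
                                               local_endemic = 0.15),
                              distance_decay_rate = 0.3,
                              homogenization_strength = 1.4,
                              cover_homogenization = 1.0,
                              endemism_cover_coupling = 1.0,
                              alpha_mean = 60,
                              individuals_per_inventory = 300,
                              seed = 42L) {
  chk_range <- function(r, name, lo = -Inf) {
    if (length(r) != 2L || r[1] > r[2]) {
      stop_betascape("betascape_config_error",
                     "%s must be an ordered (low <= high) pair", name)
    }
    if (r[1] < lo) {
      stop_betascape("betascape_config_error", "%s low must be >= %s", name, lo)
    }
  }
  chk_range(habitat_amount_range, "habitat_amount_range", 0)
  if (habitat_amount_range[2] > 1) {
    stop_betascape("betascape_config_error", "habitat_amount_range must lie in [0, 1]")
  }
  chk_range(fragmentation_nuclei_range, "fragmentation_nuclei_range", 1)
  chk_range(inventories_per_landscape_range, "inventories_per_landscape_range", 2)
  if (length(endemism_mix) != 5L || any(endemism_mix < 0) || any(endemism_mix > 1) ||
      abs(sum(endemism_mix) - 1) > 1e-9) {
    stop_betascape("betascape_domain_error",
                   "endemism_mix must be 5 probabilities in [0,1] summing to 1")
  }
  if (pool_size < 5) {
    stop_betascape("betascape_config_error", "pool_size must be >= 5")
  }
  structure(list(
    n_landscapes = as.integer(n_landscapes),
    landscape_area = landscape_area,
    cell_size = cell_size,
    habitat_amount_range = habitat_amount_range,
    fragmentation_nuclei_range = as.integer(fragmentation_nuclei_range),
    inventories_per_landscape_range = as.integer(inventories_per_landscape_range),
    pool_size = as.integer(pool_size),
    endemism_mix = endemism_mix,
    distance_decay_rate = distance_decay_rate,
    homogenization_strength = homogenization_strength,
    cover_homogenization = cover_homogenization,
    endemism_cover_coupling = endemism_cover_coupling,
    alpha_mean = alpha_mean,
    individuals_per_inventory = as.integer(individuals_per_inventory),
    seed = as.integer(seed)
  ), class = "simulation_config")
}

# Internal community-assembly constants (documented in the methods vignette):
# amplitude of the spatially autocorrelated suitability field and sd of the
# multiplicative log-normal site noise.
.betascape_sigma_field <- 1.2
.betascape_tau_site <- 0.3

#' The five endemism categories and their integer scores
#'
#' Fixed mapping: exotic = -1; not endemic with pantropical/neotropical
#' distribution = 0; not endemic with South American distribution = 1;
#' regional endemic = 2; local endemic = 3.
#'
#' @return Named integer vector of scores.
#' @export
endemism_scores <- function() {
  c(exotic = -1L,
    not_endemic_pantropical_neotropical = 0L,
    not_endemic_south_american = 1L,
    regional_endemic = 2L,
    local_endemic = 3L)
}

#' Generate a binary habitat raster by seeded cluster growth
#'
#' Neutral landscape model: `n_nuclei` random nuclei are placed, then random
#' habitat-adjacent cells are converted one at a time until exactly
#' `floor(target_cover * n_cells)` habitat cells exist. Cover is therefore
#' controlled to within one cell, and fragmentation (expected patch count)
#' rises monotonically with `n_nuclei` at fixed cover.
#'
#' @param extent landscape area in km2 (the raster is a square of side
#'   `sqrt(extent)` km).
#' @param cell_size cell size in metres.
#' @param target_cover habitat fraction in `[0, 1]`.
#' @param n_nuclei number of growth nuclei (>= 1).
#' @param seed optional RNG seed (`set.seed` is called when non-NULL).
#' @param origin lower-left corner (km).
#' @param year map year attribute.
#' @return A [habitat_raster()].
#' @export
generate_habitat_raster <- function(extent, cell_size = 30, target_cover,
                                    n_nuclei = 1L, seed = NULL,
                                    origin = c(0, 0), year = NA_integer_) {
  if (target_cover < 0 || target_cover > 1) {
    stop_betascape("betascape_domain_error", "target_cover must be in [0, 1]")
  }
  if (n_nuclei < 1) {
    stop_betascape("betascape_domain_error", "n_nuclei must be >= 1")
  }
  n_side <- round(sqrt(extent) * 1000 / cell_size)
  if (n_side < 10) {
    stop_betascape("betascape_config_error",
                   "grid too small: extent/cell_size yields %d cells per side (< 10)",
                   n_side)
  }
  if (!is.null(seed)) set.seed(seed)
  n_habitat <- floor(target_cover * n_side * n_side)
  grid <- grow_habitat_cpp(n_side, n_side, n_habitat, as.integer(n_nuclei))
  habitat_raster(grid, cell_size = cell_size, origin = origin, year = year)
}

#' Generate a species pool with endemism categories
#'
#' Each species is assigned one of the five endemism categories by independent
#' draws from `endemism_mix`; category frequencies converge to the mix as the
#' pool grows. Pool rank (1 = commonest) doubles as the abundance rank of the
#' geometric-series profile used by [generate_communities()].
#'
#' @param pool_size number of species (>= 5).
#' @param endemism_mix length-5 probabilities summing to 1 (order as in
#'   [endemism_scores()]).
#' @param seed optional RNG seed.
#' @return A data frame with columns `species_id`, `category`, `score`.
#' @export
generate_species_pool <- function(pool_size, endemism_mix, seed = NULL) {
  if (pool_size < 5) {
    stop_betascape("betascape_config_error", "pool_size must be >= 5")
  }
  if (length(endemism_mix) != 5L || abs(sum(endemism_mix) - 1) > 1e-9 ||
      any(endemism_mix < 0)) {
    stop_betascape("betascape_domain_error",
                   "endemism_mix must be 5 probabilities summing to 1")
  }
  if (!is.null(seed)) set.seed(seed)
  scores <- endemism_scores()
  category <- sample(names(scores), pool_size, replace = TRUE,
                     prob = endemism_mix)
  data.frame(
    species_id = sprintf("sp%04d", seq_len(pool_size)),
    category = category,
    score = unname(scores[category]),
    stringsAsFactors = FALSE
  )
}

# Solve the geometric-series ratio q so that the expected richness of a
# multinomial draw of N individuals from the pool profile approximates
# alpha_mean. E[S_obs] = sum_s 1 - (1 - p_s)^N is increasing in q.
solve_geometric_q <- function(pool_size, alpha_mean, n_individuals) {
  target <- min(alpha_mean, 0.9 * pool_size, 0.9 * n_individuals)
  target <- max(target, 2)
  expected_alpha <- function(q) {
    p <- q ^ (seq_len(pool_size) - 1)
    p <- p / sum(p)
    sum(1 - (1 - p) ^ n_individuals)
  }
  if (expected_alpha(0.999999) <= target) return(0.999999)
  uniroot(function(q) expected_alpha(q) - target,
          lower = 1e-6, upper = 0.999999, tol = 1e-9)$root
}

#' Generate inventory communities for one landscape
#'
#' Species weights per inventory site follow a geometric-series pool profile
#' warped by (a) a spatially autocorrelated suitability field (one random-phase
#' cosine process per species with frequency sd `distance_decay_rate` per km),
#' so expected pairwise Bray-Curtis dissimilarity rises with inter-site
#' distance; (b) a generalist-dominance exponent
#' `1 + homogenization_strength * nuclei_norm + cover_homogenization * cover`
#' concentrating abundance on common species in fragmented and high-cover
#' landscapes; and (c) an endemic-species boost `1 + endemism_cover_coupling *
#' cover` on species with score >= 2. Counts are multinomial draws of
#' `individuals_per_inventory` per site.
#'
#' @param sites numeric matrix (>= 2 rows) of site coordinates in km.
#' @param cover landscape habitat cover fraction (truth).
#' @param fragmentation landscape fragmentation propensity in [0, 1] (truth);
#'   the generator maps it to the nuclei count of the habitat raster.
#' @param pool species pool from [generate_species_pool()].
#' @param config a [simulation_config()].
#' @param seed optional RNG seed.
#' @return Integer abundance matrix, sites x species.
#' @export
generate_communities <- function(sites, cover, fragmentation, pool, config,
                                 seed = NULL) {
  sites <- as.matrix(sites)
  if (nrow(sites) < 2) {
    stop_betascape("betascape_design_error",
                   "a landscape needs at least 2 inventory sites")
  }
  if (!is.null(seed)) set.seed(seed)
  S <- nrow(pool)
  k <- nrow(sites)
  q <- solve_geometric_q(S, config$alpha_mean, config$individuals_per_inventory)
  log_base <- (seq_len(S) - 1) * log(q)

  # homogenization: generalist-dominance tilt towards low-rank (common)
  # species, plus damping of the site-level heterogeneity (community
  # convergence), both rising with fragmentation and with habitat amount
  h_eff <- config$homogenization_strength * fragmentation +
    config$cover_homogenization * cover
  tilt <- -h_eff * (seq_len(S) - 1) / (S - 1)
  damp <- exp(-h_eff)
  boost <- ifelse(pool$score >= 2L,
                  log1p(config$endemism_cover_coupling * cover), 0)

  # random-phase cosine field: corr(f_s(x), f_s(y)) = E cos(omega.(x-y))
  # declines with distance at a rate set by distance_decay_rate
  omega <- matrix(rnorm(2 * S, sd = config$distance_decay_rate), nrow = S)
  phi <- runif(S, 0, 2 * pi)
  f <- sqrt(2) * cos(sites %*% t(omega) + matrix(phi, k, S, byrow = TRUE))
  eps <- matrix(rnorm(k * S, sd = .betascape_tau_site), k, S)

  logw <- matrix(log_base + tilt + boost, k, S, byrow = TRUE) +
    sqrt(damp) * .betascape_sigma_field * f + damp * eps
  logw <- logw - apply(logw, 1, max)        # numerical safety
  w <- exp(logw)

  counts <- t(vapply(seq_len(k), function(i) {
    as.integer(rmultinom(1, config$individuals_per_inventory, w[i, ]))
  }, integer(S)))
  colnames(counts) <- pool$species_id
  counts
}

# Uniform points inside a (slightly shrunk) hexagon via rejection sampling.
sample_in_hexagon <- function(n, center, edge, shrink = 0.97) {
  verts <- hexagon_vertices(center[1], center[2], edge * shrink)
  out <- matrix(NA_real_, n, 2)
  got <- 0
  while (got < n) {
    m <- 2 * (n - got) + 8
    xs <- runif(m, min(verts[, 1]), max(verts[, 1]))
    ys <- runif(m, min(verts[, 2]), max(verts[, 2]))
    ok <- point_in_polygon(xs, ys, verts)
    take <- min(sum(ok), n - got)
    if (take > 0) {
      idx <- which(ok)[seq_len(take)]
      out[(got + 1):(got + take), ] <- cbind(xs[idx], ys[idx])
      got <- got + take
    }
  }
  out
}

#' Generate a complete synthetic landscape study
#'
#' Builds a hexagonal landscape grid, assigns each landscape a target habitat
#' cover (an evenly spaced, randomly permuted gradient over
#' `habitat_amount_range`) and a nuclei count, grows one habitat raster per
#' landscape, places 2-12 inventories uniformly inside each hexagon, and draws
#' their communities. Per-landscape RNG substreams are derived by stable
#' hashing of the landscape id, so the study is fully reproducible and adding
#' landscapes never perturbs existing ones.
#'
#' @param config a [simulation_config()].
#' @return A `synthetic_study` list: `inventories`, `abundances`, `species`,
#'   `rasters` (named list of [habitat_raster()]), `climate`, `truth`, `grid`
#'   (hexagon-grid parameters), `config`.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  pool <- generate_species_pool(config$pool_size, config$endemism_mix)

  # hexagon grid over a region with enough cells for n_landscapes
  edge <- hexagon_edge(config$landscape_area)
  w <- sqrt(3) * edge
  n_side <- ceiling(sqrt(config$n_landscapes)) + 1L
  extent <- c(0, n_side * w + w, 0, n_side * 1.5 * edge + 2 * edge)
  hexes <- hexagon_grid(extent, config$landscape_area)
  if (nrow(hexes) < config$n_landscapes) {
    stop_betascape("betascape_config_error", "hexagon grid too small")
  }
  chosen <- hexes[sort(sample.int(nrow(hexes), config$n_landscapes)), ]

  n <- config$n_landscapes
  covers <- config$habitat_amount_range[1] +
    diff(config$habitat_amount_range) *
    (if (n > 1) (seq_len(n) - 1) / (n - 1) else 0.5)
  covers <- sample(covers)
  # fragmentation propensity F in [0, 1]; the realized nuclei count follows a
  # percolation-like hump in cover (few remnant nuclei near 0% and 100%)
  frag <- runif(n)
  rng <- config$fragmentation_nuclei_range
  cap <- rng[1] + (rng[2] - rng[1]) * 4 * covers * (1 - covers)
  nuclei <- pmax(1L, as.integer(round(rng[1] + frag * (cap - rng[1]))))

  inv_rows <- list(); ab_rows <- list(); rasters <- list(); truth_rows <- list()
  side_km <- sqrt(config$landscape_area)
  for (i in seq_len(n)) {
    lid <- chosen$id[i]
    set.seed(derive_seed(config$seed, lid))
    n_inv <- sample(seq(config$inventories_per_landscape_range[1],
                        config$inventories_per_landscape_range[2]), 1)
    years <- sample(1995:2015, n_inv, replace = TRUE)
    center <- c(chosen$cx[i], chosen$cy[i])
    sites <- round(sample_in_hexagon(n_inv, center, edge), 6)
    raster <- generate_habitat_raster(
      extent = config$landscape_area, cell_size = config$cell_size,
      target_cover = covers[i], n_nuclei = nuclei[i],
      origin = center - side_km / 2, year = min(years)
    )
    counts <- generate_communities(sites, covers[i], frag[i], pool, config)
    ids <- sprintf("%s_inv%02d", lid, seq_len(n_inv))
    rownames(counts) <- ids
    inv_rows[[i]] <- data.frame(
      id = ids, landscape_id = lid, x = sites[, 1], y = sites[, 2],
      year = years, effort_ha = round(runif(n_inv, 0.1, 1.0), 2),
      dbh_cutoff_cm = 5, stringsAsFactors = FALSE
    )
    ab_rows[[i]] <- counts
    rasters[[lid]] <- raster
    truth_rows[[i]] <- data.frame(
      landscape_id = lid, target_cover = covers[i],
      realized_cover = mean(raster$values == 1L),
      fragmentation = frag[i], n_nuclei = nuclei[i],
      n_inventories = n_inv, stringsAsFactors = FALSE
    )
  }

  set.seed(derive_seed(config$seed, "climate"))
  climate <- data.frame(
    landscape_id = chosen$id,
    temperature = round(rnorm(n, 19, 2), 2),
    temperature_seasonality = round(pmax(0.5, rnorm(n, 2.5, 0.6)), 2),
    precipitation = round(pmax(600, rnorm(n, 1500, 250))),
    precipitation_seasonality = round(pmin(95, pmax(5, rnorm(n, 45, 12))), 1),
    stringsAsFactors = FALSE
  )

  truth <- do.call(rbind, truth_rows)
  truth$distance_decay_rate <- config$distance_decay_rate
  truth$homogenization_strength <- config$homogenization_strength
  truth$cover_homogenization <- config$cover_homogenization
  truth$endemism_cover_coupling <- config$endemism_cover_coupling

  structure(list(
    inventories = do.call(rbind, inv_rows),
    abundances = do.call(rbind, ab_rows),
    species = pool,
    rasters = rasters,
    climate = climate,
    truth = truth,
    grid = list(extent = extent, cell_area = config$landscape_area,
                edge = edge),
    config = config
  ), class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d landscapes, %d inventories, %d species\n",
              nrow(x$truth), nrow(x$inventories), nrow(x$species)))
  invisible(x)
}

#' Write a synthetic study to a directory of plain-text files
#'
#' Writes `inventories.csv`, `species.csv`, `abundances.csv` (wide, first
#' column `id`), `climate.csv`, `truth.csv`, `meta.csv` (grid parameters and
#' seed) and one ESRI ASCII raster per landscape under `rasters/`.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(file.path(dir, "rasters"), recursive = TRUE, showWarnings = FALSE)
  write.csv(study$inventories, file.path(dir, "inventories.csv"), row.names = FALSE)
  write.csv(study$species, file.path(dir, "species.csv"), row.names = FALSE)
  ab <- data.frame(id = rownames(study$abundances), study$abundances,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(ab, file.path(dir, "abundances.csv"), row.names = FALSE)
  write.csv(study$climate, file.path(dir, "climate.csv"), row.names = FALSE)
  write.csv(study$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  meta <- data.frame(
    key = c("extent_xmin", "extent_xmax", "extent_ymin", "extent_ymax",
            "cell_area", "seed"),
    value = c(study$grid$extent, study$grid$cell_area, study$config$seed)
  )
  write.csv(meta, file.path(dir, "meta.csv"), row.names = FALSE)
  for (lid in names(study$rasters)) {
    write_asc(study$rasters[[lid]], file.path(dir, "rasters", paste0(lid, ".asc")))
  }
  invisible(dir)
}
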