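#' Pipeline configuration
#'
#' Bundles stage toggles, the embedded simulation config, null-model
#' replicates, and the analysis thresholds. Threshold defaults are the
#' study-design constants of the analysis: minimum effort 0.10 ha, DBH cutoff
#' 5 cm, correlation screen r = 0.70, Delta-AIC 2, minimum 2 inventories per
#' landscape.
#'
#' @param sim a [simulation_config()].
#' @param stages character vector of stages to run, in order, from
#'   `c("simulate", "design", "metrics", "beta", "endemism", "model")`.
#' @param n_reps Raup-Crick null replicates per pair.
#' @param thresholds named list: `effort`, `dbh`, `r`, `delta_aic`,
#'   `min_inventories`.
#' @param connectivity patch connectivity (8 or 4).
#' @param interaction interaction pair for the models.
#' @param responses responses to model.
#' @param seed master seed for the analysis stages (the simulation uses
#'   `sim$seed`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            stages = c("simulate", "design", "metrics",
                                       "beta", "endemism", "model"),
                            n_reps = 999,
                            thresholds = list(effort = 0.10, dbh = 5,
                                              r = 0.70, delta_aic = 2,
                                              min_inventories = 2),
                            connectivity = 8,
                            interaction = c("habitat_cover", "n_patches"),
                            responses = c("beta_total", "rc_rescaled",
                                          "endemism"),
                            seed = 1L) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(sim = sim, stages = stages, n_reps = n_reps,
                 thresholds = thresholds, connectivity = connectivity,
                 interaction = interaction, responses = responses,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Build a pipeline configuration from a structured config file
#'
#' Reads a JSON file whose top level may contain any [pipeline_config()]
#' argument (`stages`, `n_reps`, `thresholds`, `connectivity`,
#' `interaction`, `responses`, `seed`) plus a `sim` block with
#' [simulation_config()] fields (key names exactly as the function
#' arguments). Missing keys keep their defaults.
#'
#' @param path path to a JSON config file.
#' @return A [pipeline_config()].
#' @export
pipeline_config_from_file <- function(path) {
  if (!file.exists(path)) {
    stop_betascape("betascape_config_error", "config file not found: %s", path)
  }
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop_betascape("betascape_config_error",
                   "the jsonlite package is required to read config files")
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  sim_args <- if (!is.null(raw$sim)) raw$sim else list()
  bad <- setdiff(names(sim_args), names(formals(simulation_config)))
  if (length(bad)) {
    stop_betascape("betascape_config_error",
                   "unknown simulation config key(s): %s",
                   paste(bad, collapse = ", "))
  }
  sim <- do.call(simulation_config, sim_args)
  top <- raw[setdiff(names(raw), "sim")]
  bad <- setdiff(names(top), setdiff(names(formals(pipeline_config)), "sim"))
  if (length(bad)) {
    stop_betascape("betascape_config_error",
                   "unknown pipeline config key(s): %s",
                   paste(bad, collapse = ", "))
  }
  if (!is.null(top$thresholds)) top$thresholds <- as.list(top$thresholds)
  do.call(pipeline_config, c(list(sim = sim), top))
}

#' Read a study written by [write_study()]
#'
#' @param dir directory holding `inventories.csv`, `species.csv`,
#'   `abundances.csv`, `climate.csv`, `truth.csv`, `meta.csv` and `rasters/`.
#' @return A `synthetic_study`.
#' @export
read_study <- function(dir) {
  need <- c("inventories.csv", "species.csv", "abundances.csv",
            "climate.csv", "truth.csv", "meta.csv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    stop_betascape("betascape_data_error", "missing study inputs: %s",
                   paste(missing, collapse = ", "))
  }
  inv <- read.csv(file.path(dir, "inventories.csv"), stringsAsFactors = FALSE)
  species <- read.csv(file.path(dir, "species.csv"), stringsAsFactors = FALSE)
  ab <- read.csv(file.path(dir, "abundances.csv"), check.names = FALSE,
                 stringsAsFactors = FALSE)
  abundances <- as.matrix(ab[, -1, drop = FALSE])
  rownames(abundances) <- ab[[1]]
  climate <- read.csv(file.path(dir, "climate.csv"), stringsAsFactors = FALSE)
  truth <- read.csv(file.path(dir, "truth.csv"), stringsAsFactors = FALSE)
  meta <- read.csv(file.path(dir, "meta.csv"), stringsAsFactors = FALSE)
  getm <- function(k) meta$value[meta$key == k]
  extent <- c(getm("extent_xmin"), getm("extent_xmax"),
              getm("extent_ymin"), getm("extent_ymax"))
  cell_area <- getm("cell_area")
  raster_files <- list.files(file.path(dir, "rasters"), pattern = "\\.asc$",
                             full.names = TRUE)
  rasters <- lapply(raster_files, read_asc)
  names(rasters) <- sub("\\.asc$", "", basename(raster_files))
  structure(list(inventories = inv, abundances = abundances,
                 species = species, rasters = rasters, climate = climate,
                 truth = truth,
                 grid = list(extent = extent, cell_area = cell_area,
                             edge = hexagon_edge(cell_area)),
                 config = NULL),
            class = "synthetic_study")
}

# Restrict a study to the inventories/landscapes retained by the design stage.
subset_study <- function(study, membership) {
  keep_inv <- membership$inventory_id
  keep_l <- unique(membership$landscape_id)
  study$inventories <- study$inventories[study$inventories$id %in% keep_inv, ]
  study$inventories$landscape_id <-
    membership$landscape_id[match(study$inventories$id, membership$inventory_id)]
  study$abundances <- study$abundances[keep_inv, , drop = FALSE]
  study$truth <- study$truth[study$truth$landscape_id %in% keep_l, ]
  study$climate <- study$climate[study$climate$landscape_id %in% keep_l, ]
  study$rasters <- study$rasters[intersect(names(study$rasters), keep_l)]
  study
}

#' Analyze a study in memory: metrics, beta diversity, endemism, models
#'
#' The computational core of the pipeline, without file I/O. Applies the
#' inventory filters and landscape assignment, computes all per-landscape
#' predictors and responses, screens predictors by Pearson correlation, and
#' runs all-subsets AIC selection per requested response (beta regression for
#' the two beta-diversity responses, Gaussian for endemism).
#'
#' @param study a `synthetic_study`.
#' @param config a [pipeline_config()].
#' @return List: `design` (membership data frame), `metrics`, `beta`,
#'   `endemism`, `table` (merged landscape table), `screen`, `pca`,
#'   `selections` (one `selection_table` per response), `diagnostics`.
#' @export
analyze_study <- function(study, config = pipeline_config()) {
  th <- config$thresholds
  flt <- filter_inventories(study$inventories, study$abundances, study$species,
                            min_effort = th$effort, min_dbh = th$dbh)
  hexes <- hexagon_grid(study$grid$extent, study$grid$cell_area)
  units <- assign_landscapes(flt$kept, hexes,
                             min_inventories = th$min_inventories)
  membership <- attr(units, "membership")
  ref_years <- vapply(units, function(u) u$reference_year, numeric(1))
  membership$reference_year <- ref_years[membership$landscape_id]
  study <- subset_study(study, membership)

  metrics <- landscape_metrics_table(study, connectivity = config$connectivity)
  beta <- beta_diversity_table(study, n_reps = config$n_reps,
                               seed = config$seed)
  endem <- endemism_table(study)$landscapes

  tab <- Reduce(function(a, b) merge(a, b, by = "landscape_id"),
                list(metrics, beta, endem))

  predictors_all <- c("habitat_cover", "n_patches", "mean_patch_size",
                      "enn_mn", "mean_spatial_distance", "temperature",
                      "temperature_seasonality", "precipitation",
                      "precipitation_seasonality")
  pred_tab <- tab[, predictors_all]
  cc <- complete.cases(pred_tab)
  screen <- pearson_screen(pred_tab[cc, ], threshold = th$r)
  retained <- screen$retained
  pca <- pca_landscapes(standardize_predictors(pred_tab[cc, retained]))

  interaction <- config$interaction
  if (!is.null(interaction) && !all(interaction %in% retained)) {
    interaction <- NULL
  }
  selections <- list()
  diagnostics <- list()
  coords <- aggregate(cbind(x, y) ~ landscape_id, data = study$inventories,
                      FUN = mean)
  for (resp in config$responses) {
    family <- if (resp == "endemism") "gaussian" else "beta_logit"
    sel <- all_subsets(tab, resp, retained, family = family,
                       interaction = interaction)
    selections[[resp]] <- sel
    fit <- attr(sel, "fits")[[sel$model[1]]]
    terms <- selection_effects(sel, 1)$term
    main_terms <- terms[!grepl(":", terms)]
    used <- tab[complete.cases(tab[, c(resp, retained)]), ]
    xy <- coords[match(used$landscape_id, coords$landscape_id), c("x", "y")]
    diagnostics[[resp]] <- list(
      vif = if (length(main_terms) >= 2) {
        vif(standardize_predictors(used[main_terms]))
      } else NULL,
      moran = morans_i(fit$residuals, xy)
    )
  }
  list(design = membership, metrics = metrics, beta = beta, endemism = endem,
       table = tab, screen = screen, pca = pca, selections = selections,
       diagnostics = diagnostics)
}

write_stage <- function(dir, stage, tables) {
  sdir <- file.path(dir, stage)
  dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (nm in names(tables)) {
    p <- file.path(sdir, paste0(nm, ".csv"))
    write.csv(tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  paths
}

#' Run the full pipeline, writing one directory per stage
#'
#' Executes the enabled stages in order (simulate, design, metrics, beta,
#' endemism, model). Each stage writes its tables as CSV plus a shared
#' `manifest.csv` (file, md5, stage) and `run_info.csv` (seed, thresholds,
#' package version), so a rerun with identical config reproduces
#' byte-identical outputs. When the simulate stage is disabled, `input_dir`
#' must point at an existing study written by [write_study()].
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created).
#' @param input_dir study directory used when `"simulate"` is not in
#'   `config$stages`.
#' @return `out_dir`, invisibly; the in-memory results as
#'   `attr(, "results")`.
#' @export
run_pipeline <- function(config, out_dir, input_dir = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  all_paths <- character()
  if ("simulate" %in% config$stages) {
    study <- generate_study(config$sim)
    write_study(study, file.path(out_dir, "simulate"))
    all_paths <- c(all_paths,
                   list.files(file.path(out_dir, "simulate"),
                              recursive = TRUE, full.names = TRUE))
  } else {
    if (is.null(input_dir)) {
      stop_betascape("betascape_config_error",
                     "simulate disabled: input_dir is required")
    }
    study <- read_study(input_dir)
  }
  res <- analyze_study(study, config)

  all_paths <- c(all_paths, write_stage(out_dir, "design",
                                        list(membership = res$design)))
  all_paths <- c(all_paths, write_stage(out_dir, "metrics",
                                        list(metrics = res$metrics)))
  all_paths <- c(all_paths, write_stage(out_dir, "beta",
                                        list(beta = res$beta)))
  all_paths <- c(all_paths, write_stage(out_dir, "endemism",
                                        list(endemism = res$endemism)))
  model_tabs <- list(
    screen = data.frame(variable = res$screen$dropped$variable,
                        partner = res$screen$dropped$partner,
                        r = res$screen$dropped$r),
    retained = data.frame(variable = res$screen$retained),
    pca = data.frame(axis = seq_along(res$pca$var_explained),
                     var_explained = res$pca$var_explained)
  )
  for (resp in names(res$selections)) {
    sel <- res$selections[[resp]]
    model_tabs[[paste0("selection_", resp)]] <- as.data.frame(sel)
    co <- do.call(rbind, lapply(which(sel$best), function(rk) {
      eff <- selection_effects(sel, rk)
      if (nrow(eff) == 0) return(NULL)      # intercept-only model in best set
      data.frame(rank = rk, eff, stringsAsFactors = FALSE)
    }))
    if (is.null(co)) {
      co <- data.frame(rank = integer(), term = character(),
                       estimate = numeric(), se = numeric(), p = numeric())
    }
    model_tabs[[paste0("effects_", resp)]] <- co
  }
  all_paths <- c(all_paths, write_stage(out_dir, "model", model_tabs))

  manifest <- data.frame(
    file = sub(paste0("^", out_dir, "/?"), "", all_paths),
    md5 = unname(tools::md5sum(all_paths)),
    stringsAsFactors = FALSE
  )
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  info <- data.frame(
    key = c("seed", "sim_seed", "n_reps", "effort_min_ha", "dbh_min_cm",
            "r_threshold", "delta_aic", "min_inventories", "version"),
    value = c(config$seed,
              if (!is.null(config$sim)) config$sim$seed else NA,
              config$n_reps, config$thresholds$effort, config$thresholds$dbh,
              config$thresholds$r, config$thresholds$delta_aic,
              config$thresholds$min_inventories,
              as.character(utils::packageVersion("betascape")))
  )
  write.csv(info, file.path(out_dir, "run_info.csv"), row.names = FALSE)
  out <- out_dir
  attr(out, "results") <- res
  invisible(out)
}

#' Summary statistics of a design-stage membership table
#'
#' @param membership data frame with `landscape_id` and `inventory_id` (one
#'   row per retained inventory).
#' @return List: `n_landscapes`, `n_inventories`, `mean_per_landscape`
#'   (2 decimals), `min_per_landscape`, `max_per_landscape`.
#' @export
design_summary <- function(membership) {
  counts <- table(membership$landscape_id)
  list(
    n_landscapes = length(counts),
    n_inventories = nrow(membership),
    mean_per_landscape = round(nrow(membership) / length(counts), 2),
    min_per_landscape = min(counts),
    max_per_landscape = max(counts)
  )
}

#' Human-readable report of a completed pipeline run
#'
#' @param run_dir directory written by [run_pipeline()].
#' @return Character vector of report lines (also printed).
#' @export
summarize_run <- function(run_dir) {
  need <- c("design/membership.csv", "metrics/metrics.csv", "beta/beta.csv",
            "endemism/endemism.csv", "run_info.csv")
  gaps <- need[!file.exists(file.path(run_dir, need))]
  if (length(gaps)) {
    stop_betascape("betascape_report_error", "missing stage outputs: %s",
                   paste(gaps, collapse = ", "))
  }
  membership <- read.csv(file.path(run_dir, "design", "membership.csv"))
  metrics <- read.csv(file.path(run_dir, "metrics", "metrics.csv"))
  info <- read.csv(file.path(run_dir, "run_info.csv"))
  ds <- design_summary(membership)
  lines <- c(
    "betascape run summary",
    "=====================",
    sprintf("landscapes: %d", ds$n_landscapes),
    sprintf("inventories: %d (per landscape mean %.2f, min %d, max %d)",
            ds$n_inventories, ds$mean_per_landscape,
            ds$min_per_landscape, ds$max_per_landscape),
    sprintf("habitat cover range: %.1f%% - %.1f%%",
            min(metrics$habitat_cover), max(metrics$habitat_cover)),
    sprintf("seed: %s | null reps: %s | thresholds: effort >= %s ha, dbh >= %s cm, r <= %s, dAIC <= %s, >= %s inventories",
            info$value[info$key == "seed"], info$value[info$key == "n_reps"],
            info$value[info$key == "effort_min_ha"],
            info$value[info$key == "dbh_min_cm"],
            info$value[info$key == "r_threshold"],
            info$value[info$key == "delta_aic"],
            info$value[info$key == "min_inventories"])
  )
  for (resp in c("beta_total", "rc_rescaled", "endemism")) {
    sel_path <- file.path(run_dir, "model", paste0("selection_", resp, ".csv"))
    eff_path <- file.path(run_dir, "model", paste0("effects_", resp, ".csv"))
    if (!file.exists(sel_path)) next
    sel <- read.csv(sel_path)
    best <- sel[sel$best, ]
    lines <- c(lines, "",
               sprintf("best models for %s (dAIC <= 2): %d of %d",
                       resp, nrow(best), nrow(sel)))
    lines <- c(lines, sprintf("  #%d AIC %.2f dAIC %.2f R2 %.2f: %s",
                              best$rank, best$aic, best$delta_aic, best$r2,
                              best$model))
    if (file.exists(eff_path)) {
      eff <- read.csv(eff_path)
      e1 <- eff[eff$rank == 1, ]
      lines <- c(lines, sprintf("  rank-1 effects: %s",
                                paste(sprintf("%s %+0.2f (p=%.3g)", e1$term,
                                              e1$estimate, e1$p),
                                      collapse = "; ")))
    }
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
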