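#' Habitat cover of a landscape
#'
#' Percentage of valid (non-nodata) cells whose centre lies in the polygon
#' that are habitat.
#'
#' @param raster a [habitat_raster()].
#' @param polygon optional clip polygon (two-column vertex matrix); `NULL`
#'   uses the whole raster.
#' @return Cover in percent (0-100).
#' @export
habitat_cover <- function(raster, polygon = NULL) {
  v <- clip_raster_values(raster, polygon)
  n_valid <- sum(!is.na(v))
  if (n_valid == 0) {
    stop_betascape("betascape_metric_error",
                   "no valid raster cells inside the polygon")
  }
  100 * sum(v == 1L, na.rm = TRUE) / n_valid
}

#' Habitat patches of a landscape
#'
#' Connected components of habitat cells (after the cell-centre-in-polygon
#' clip) under queen (8, default) or rook (4) connectivity. Mean patch size is
#' total habitat area divided by the number of patches, in hectares, so
#' `mean_patch_size * n_patches` recovers the habitat area exactly.
#'
#' @param raster a [habitat_raster()].
#' @param polygon optional clip polygon.
#' @param connectivity 8 (queen) or 4 (rook).
#' @return A list: `n_patches`, `mean_patch_size` (ha, `NA` when no habitat),
#'   `labels` (integer matrix, 0 = background).
#' @export
patches <- function(raster, polygon = NULL, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) {
    stop_betascape("betascape_config_error", "connectivity must be 4 or 8")
  }
  v <- clip_raster_values(raster, polygon)
  v[is.na(v)] <- 0L
  res <- label_patches_cpp(v, as.integer(connectivity))
  n <- res$n_patches
  n_habitat <- sum(v == 1L)
  mps <- if (n > 0) n_habitat * raster$cell_size^2 / 1e4 / n else NA_real_
  list(n_patches = n, mean_patch_size = mps, labels = res$labels)
}

#' Mean Euclidean nearest-neighbour distance among patches (ENN_MN)
#'
#' For each patch, the minimum distance between its border-cell centres and
#' any other patch's border-cell centres; the metric is the mean over patches.
#' Undefined (returns `NA`, not an error) when fewer than two patches exist.
#'
#' @param labels patch label matrix from [patches()].
#' @param cell_size cell size in metres.
#' @return ENN_MN in metres, or `NA_real_`.
#' @export
enn_mn <- function(labels, cell_size) {
  n <- max(labels)
  enn_mn_cpp(labels, as.integer(n), cell_size)
}

#' Mean pairwise spatial distance among inventory coordinates
#'
#' Mean over all unordered pairs of point-to-point distance: planar Euclidean
#' for km coordinates, haversine great-circle (R = 6371 km) for lon/lat.
#'
#' @param coords two-column matrix of coordinates (>= 2 rows).
#' @param mode `"planar"` (km in, km out) or `"lonlat"` (degrees in, km out).
#' @return Mean pairwise distance in km.
#' @export
mean_spatial_distance <- function(coords, mode = c("planar", "lonlat")) {
  mode <- match.arg(mode)
  coords <- as.matrix(coords)
  if (nrow(coords) < 2) {
    stop_betascape("betascape_design_error",
                   "mean spatial distance needs at least 2 points")
  }
  if (mode == "planar") {
    return(mean(dist(coords)))
  }
  n <- nrow(coords)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  mean(haversine_km(coords[pairs[, 1], 1], coords[pairs[, 1], 2],
                    coords[pairs[, 2], 1], coords[pairs[, 2], 2]))
}

#' Haversine great-circle distance
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees.
#' @param radius sphere radius in km (default 6371).
#' @return Distance(s) in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2, radius = 6371) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * radius * asin(pmin(1, sqrt(a)))
}

#' Zonal climate means over a landscape
#'
#' Per-variable mean over raster cells with centre in the polygon, nodata
#' excluded.
#'
#' @param climate_rasters named list of [habitat_raster()]-like rasters whose
#'   `values` are numeric climate grids (NA = nodata).
#' @param polygon optional clip polygon.
#' @return Named numeric vector, one mean per raster.
#' @export
zonal_climate <- function(climate_rasters, polygon = NULL) {
  vapply(climate_rasters, function(r) {
    v <- r$values
    if (!is.null(polygon)) {
      cc <- raster_cell_centers(r)
      xs <- rep(cc$x, each = nrow(v))
      ys <- rep(cc$y, times = ncol(v))
      keep <- matrix(point_in_polygon(xs, ys, polygon), nrow = nrow(v))
      v[!keep] <- NA
    }
    if (all(is.na(v))) {
      stop_betascape("betascape_metric_error",
                     "no valid climate cells inside the polygon")
    }
    mean(v, na.rm = TRUE)
  }, numeric(1))
}

#' Select the habitat raster matching a landscape's reference year
#'
#' Exact year match when available; otherwise the nearest year at or before
#' the reference year; otherwise the earliest available raster (with a
#' warning).
#'
#' @param rasters list of [habitat_raster()] with `year` set.
#' @param reference_year the landscape's reference (oldest inventory) year.
#' @return One [habitat_raster()].
#' @export
reference_raster <- function(rasters, reference_year) {
  if (length(rasters) == 0) {
    stop_betascape("betascape_config_error", "no rasters supplied")
  }
  years <- vapply(rasters, function(r) r$year, integer(1))
  exact <- which(years == reference_year)
  if (length(exact)) return(rasters[[exact[1]]])
  before <- which(years <= reference_year)
  if (length(before)) {
    return(rasters[[before[which.max(years[before])]]])
  }
  warning(sprintf("no raster at or before %d; using earliest (%d)",
                  reference_year, min(years)))
  rasters[[which.min(years)]]
}

# values may be percent-like columns; keep NA for undefined metrics
#' Per-landscape metrics table for a synthetic study
#'
#' Computes habitat cover, patch metrics (queen connectivity by default),
#' ENN_MN, and the mean pairwise spatial distance among member inventories for
#' every landscape of a study, and joins the per-landscape climate.
#'
#' @param study a `synthetic_study` from [generate_study()].
#' @param connectivity 8 or 4.
#' @return Data frame, one row per landscape: `landscape_id`, `habitat_cover`
#'   (%), `n_patches`, `mean_patch_size` (ha), `enn_mn` (m),
#'   `mean_spatial_distance` (km) and the four climate variables.
#' @export
landscape_metrics_table <- function(study, connectivity = 8) {
  ids <- study$truth$landscape_id
  rows <- lapply(ids, function(lid) {
    r <- study$rasters[[lid]]
    p <- patches(r, connectivity = connectivity)
    inv <- study$inventories[study$inventories$landscape_id == lid, ]
    data.frame(
      landscape_id = lid,
      habitat_cover = habitat_cover(r),
      n_patches = p$n_patches,
      mean_patch_size = p$mean_patch_size,
      enn_mn = enn_mn(p$labels, r$cell_size),
      mean_spatial_distance = mean_spatial_distance(cbind(inv$x, inv$y)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  merge(out, study$climate, by = "landscape_id", sort = TRUE)
}
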