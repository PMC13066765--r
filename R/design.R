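#' Edge length of a hexagon of given area
#'
#' For a regular hexagon of area \eqn{A = (3\sqrt{3}/2) a^2}, the edge is
#' \eqn{a = \sqrt{2A / (3\sqrt{3})}}. For the 100-km2 landscape unit this is
#' 6.2040 km.
#'
#' @param cell_area hexagon area (km2).
#' @return Edge length in the same linear units.
#' @export
hexagon_edge <- function(cell_area) {
  if (cell_area <= 0) {
    stop_betascape("betascape_config_error", "cell_area must be > 0")
  }
  sqrt(2 * cell_area / (3 * sqrt(3)))
}

#' Vertices of a pointy-top regular hexagon
#'
#' @param cx,cy centre coordinates.
#' @param edge edge length (= circumradius).
#' @return 6 x 2 matrix of vertices, counter-clockwise from the top vertex.
#' @export
hexagon_vertices <- function(cx, cy, edge) {
  ang <- pi / 180 * (90 + 60 * (0:5))
  cbind(cx + edge * cos(ang), cy + edge * sin(ang))
}

#' Regular hexagonal tessellation of an extent
#'
#' Pointy-top hexagons with the grid origin anchored at the extent's minimum
#' corner (both conventions fixed for reproducibility; the landscape unit of
#' the analysis is one hexagon). Centres are laid out on the standard offset
#' lattice: horizontal spacing `sqrt(3) * a`, vertical spacing `1.5 * a`, odd
#' rows shifted by half a width. Enough rows/columns are generated to cover
#' the extent completely.
#'
#' @param extent numeric length-4 vector `c(xmin, xmax, ymin, ymax)`.
#' @param cell_area hexagon area (same squared units as the extent; km2 for
#'   planar-km coordinates).
#' @return A data frame (`hexagon_grid`) with columns `id`, `row`, `col`,
#'   `cx`, `cy`; the edge length is stored in `attr(, "edge")` and the extent
#'   in `attr(, "extent")`.
#' @export
hexagon_grid <- function(extent, cell_area) {
  if (length(extent) != 4L || extent[1] >= extent[2] || extent[3] >= extent[4]) {
    stop_betascape("betascape_config_error",
                   "extent must be c(xmin, xmax, ymin, ymax), non-degenerate")
  }
  a <- hexagon_edge(cell_area)
  w <- sqrt(3) * a
  n_rows <- ceiling((extent[4] - extent[3]) / (1.5 * a)) + 2L
  n_cols <- ceiling((extent[2] - extent[1]) / w) + 2L
  rows <- rep(seq_len(n_rows) - 1L, each = n_cols)
  cols <- rep(seq_len(n_cols) - 1L, times = n_rows)
  cx <- extent[1] + cols * w + ifelse(rows %% 2L == 1L, w / 2, 0)
  cy <- extent[3] + rows * 1.5 * a
  out <- data.frame(
    id = sprintf("H%03d_%03d", rows, cols),
    row = rows, col = cols, cx = cx, cy = cy,
    stringsAsFactors = FALSE
  )
  attr(out, "edge") <- a
  attr(out, "extent") <- extent
  class(out) <- c("hexagon_grid", "data.frame")
  out
}

#' Assign points to hexagons of a grid
#'
#' A point belongs to the hexagon whose centre is nearest (the Voronoi diagram
#' of a hexagonal lattice is the hexagon tiling itself, so this is exact
#' containment). Boundary ties are broken deterministically towards the lowest
#' hexagon id, which realises a half-open edge convention: every point belongs
#' to exactly one hexagon.
#'
#' @param x,y point coordinates.
#' @param hexes a [hexagon_grid()].
#' @return Integer vector of row indices into `hexes`.
#' @export
hexagon_lookup <- function(x, y, hexes) {
  vapply(seq_along(x), function(i) {
    d2 <- (hexes$cx - x[i])^2 + (hexes$cy - y[i])^2
    which(d2 == min(d2))[1]            # lowest index on exact ties
  }, integer(1))
}

#' Filter forest inventories by sampling-consistency rules
#'
#' Keeps inventories with sampling effort >= `min_effort` ha, a DBH inclusion
#' cutoff >= `min_dbh` cm, and complete species data (no missing abundance and
#' every positive-abundance species resolvable in the species table). Dropped
#' inventories carry a single machine-readable reason code, the first failed
#' rule in the fixed order effort, dbh, completeness.
#'
#' @param inventories data frame with columns `id`, `effort_ha`,
#'   `dbh_cutoff_cm` (plus any others, preserved).
#' @param abundances abundance matrix with rownames matching `inventories$id`.
#' @param species optional species table (`species_id` column); when supplied,
#'   every species with positive abundance must be resolvable.
#' @param min_effort minimum sampling effort in ha (default 0.10).
#' @param min_dbh minimum DBH cutoff in cm (default 5).
#' @return A list with `kept` (data frame, input order preserved) and
#'   `dropped` (data frame `id`, `reason`).
#' @export
filter_inventories <- function(inventories, abundances = NULL, species = NULL,
                               min_effort = 0.10, min_dbh = 5) {
  req <- c("id", "effort_ha", "dbh_cutoff_cm")
  if (!all(req %in% names(inventories))) {
    stop_betascape("betascape_ingestion_error",
                   "inventory table must have columns: %s",
                   paste(req, collapse = ", "))
  }
  bad_row <- is.na(inventories$effort_ha) | is.na(inventories$dbh_cutoff_cm)
  if (any(bad_row)) {
    stop_betascape("betascape_ingestion_error",
                   "unparseable inventory row(s): %s",
                   paste(inventories$id[bad_row], collapse = ", "))
  }
  reason <- rep(NA_character_, nrow(inventories))
  reason[inventories$effort_ha < min_effort] <- "effort"
  need_dbh <- is.na(reason) & inventories$dbh_cutoff_cm < min_dbh
  reason[need_dbh] <- "dbh"
  if (!is.null(abundances)) {
    for (i in which(is.na(reason))) {
      id <- inventories$id[i]
      if (!id %in% rownames(abundances)) {
        reason[i] <- "completeness"
        next
      }
      row <- abundances[id, ]
      if (anyNA(row)) {
        reason[i] <- "completeness"
      } else if (!is.null(species)) {
        pos <- colnames(abundances)[which(row > 0)]
        if (!all(pos %in% species$species_id)) reason[i] <- "completeness"
      }
    }
  }
  keep <- is.na(reason)
  list(
    kept = inventories[keep, , drop = FALSE],
    dropped = data.frame(id = inventories$id[!keep], reason = reason[!keep],
                         stringsAsFactors = FALSE)
  )
}

#' Assign filtered inventories to landscape units
#'
#' Each inventory joins the unique hexagon containing its coordinates;
#' hexagons with fewer than `min_inventories` members are discarded. The
#' reference year of a landscape is the *minimum* (oldest) inventory year
#' among its members, which later selects the matching habitat raster.
#'
#' @param inventories filtered inventory data frame (`id`, `x`, `y`, `year`).
#' @param hexes a [hexagon_grid()].
#' @param min_inventories minimum inventories per landscape (default 2).
#' @return A list of `landscape_unit`s: each has `id`, `center`, `polygon`,
#'   `inventory_ids`, `reference_year`. Also returned as a membership data
#'   frame in `attr(, "membership")`.
#' @export
assign_landscapes <- function(inventories, hexes, min_inventories = 2) {
  idx <- hexagon_lookup(inventories$x, inventories$y, hexes)
  edge0 <- attr(hexes, "edge")
  outside <- vapply(seq_len(nrow(inventories)), function(i) {
    h <- hexes[idx[i], ]
    # nearest-centre cell == containing hexagon when the point is covered by
    # the grid; verify with a tolerance-inflated polygon test
    !point_in_polygon(inventories$x[i], inventories$y[i],
                      hexagon_vertices(h$cx, h$cy, edge0 * (1 + 1e-9)))
  }, logical(1))
  if (any(outside)) {
    stop_betascape("betascape_assignment_error",
                   "inventories outside the hexagon grid: %s",
                   paste(inventories$id[outside], collapse = ", "))
  }
  hid <- hexes$id[idx]
  keep_ids <- names(which(table(hid) >= min_inventories))
  edge <- attr(hexes, "edge")
  units <- lapply(sort(keep_ids), function(id) {
    members <- inventories[hid == id, , drop = FALSE]
    h <- hexes[hexes$id == id, ]
    structure(list(
      id = id,
      center = c(h$cx, h$cy),
      polygon = hexagon_vertices(h$cx, h$cy, edge),
      inventory_ids = members$id,
      reference_year = min(members$year)
    ), class = "landscape_unit")
  })
  names(units) <- sort(keep_ids)
  membership <- data.frame(
    landscape_id = hid, inventory_id = inventories$id,
    stringsAsFactors = FALSE
  )
  membership <- membership[membership$landscape_id %in% keep_ids, ]
  attr(units, "membership") <- membership[order(membership$landscape_id), ]
  units
}
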