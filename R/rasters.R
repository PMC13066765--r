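#' Binary habitat raster
#'
#' A minimal single-band raster container for binary habitat maps: an integer
#' matrix of 0 (non-habitat), 1 (habitat) and `NA` (nodata), plus cell size in
#' metres, the coordinates of the lower-left corner, and the map year. Row 1
#' of `values` is the *bottom* row of the grid (origin is the lower-left
#' corner); columns run west to east.
#'
#' @param values integer matrix in \{0, 1, NA\}.
#' @param cell_size cell edge length in metres (> 0).
#' @param origin numeric length-2 vector, lower-left corner `(x, y)`. Units
#'   are kilometres in planar mode (the synthetic default).
#' @param year calendar year of the map (used by [reference_raster()]).
#' @return An object of class `habitat_raster`.
#' @export
habitat_raster <- function(values, cell_size = 30, origin = c(0, 0),
                           year = NA_integer_) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  bad <- !(values %in% c(0L, 1L) | is.na(values))
  if (any(bad)) {
    stop_betascape("betascape_domain_error",
                   "habitat raster values must be 0, 1 or NA")
  }
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    stop_betascape("betascape_config_error", "cell_size must be a positive number")
  }
  structure(
    list(values = values, cell_size = cell_size,
         origin = as.numeric(origin), year = as.integer(year)),
    class = "habitat_raster"
  )
}

#' @export
print.habitat_raster <- function(x, ...) {
  n_hab <- sum(x$values == 1L, na.rm = TRUE)
  cat(sprintf("<habitat_raster> %d x %d cells @ %g m, year %s, %d habitat cells\n",
              nrow(x$values), ncol(x$values), x$cell_size,
              ifelse(is.na(x$year), "?", x$year), n_hab))
  invisible(x)
}

#' Cell-centre coordinates of a habitat raster
#'
#' @param raster a [habitat_raster()].
#' @param units `"km"` (origin units, assuming a kilometre origin) or `"m"`.
#' @return A list with vectors `x` (per column) and `y` (per row) of cell
#'   centres in origin units.
#' @keywords internal
raster_cell_centers <- function(raster, units = "km") {
  step <- raster$cell_size / 1000      # origin is in km in planar mode
  nr <- nrow(raster$values)
  nc <- ncol(raster$values)
  list(x = raster$origin[1] + (seq_len(nc) - 0.5) * step,
       y = raster$origin[2] + (seq_len(nr) - 0.5) * step)
}

#' Write a habitat raster as an ESRI ASCII grid
#'
#' Plain-text single-band raster exchange format (`.asc`): a 6-line header
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`)
#' followed by rows top-down. The year is stored as a `# year:` comment line
#' appended after the data (ignored by other readers).
#'
#' @param raster a [habitat_raster()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_asc <- function(raster, path) {
  v <- raster$values
  v[is.na(v)] <- -9999L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", raster$origin[1]),
    sprintf("yllcorner %.10g", raster$origin[2]),
    sprintf("cellsize %.10g", raster$cell_size),
    "NODATA_value -9999"
  ), con)
  for (r in rev(seq_len(nrow(v)))) {      # .asc rows run north to south
    writeLines(paste(v[r, ], collapse = " "), con)
  }
  writeLines(sprintf("# year: %s", ifelse(is.na(raster$year), "NA", raster$year)),
             con)
  invisible(path)
}

#' Read an ESRI ASCII grid as a habitat raster
#'
#' @param path path to a `.asc` file written by [write_asc()] (or any ESRI
#'   ASCII grid with values in \{0, 1, NODATA\}).
#' @return A [habitat_raster()].
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  get <- function(key) {
    ln <- hdr[grepl(paste0("^", key), hdr, ignore.case = TRUE)]
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  ncols <- get("ncols"); nrows <- get("nrows")
  xll <- get("xllcorner"); yll <- get("yllcorner")
  cellsize <- get("cellsize"); nodata <- get("NODATA_value")
  body <- lines[-(1:6)]
  year <- NA_integer_
  is_comment <- grepl("^#", body)
  if (any(is_comment)) {
    ytxt <- sub("^# year:\\s*", "", body[is_comment][1])
    year <- suppressWarnings(as.integer(ytxt))
    body <- body[!is_comment]
  }
  vals <- as.integer(unlist(strsplit(trimws(body), "\\s+")))
  m <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  m[m == nodata] <- NA_integer_
  m <- m[rev(seq_len(nrows)), , drop = FALSE]   # back to bottom-up storage
  habitat_raster(m, cell_size = cellsize, origin = c(xll, yll), year = year)
}

#' Test which points fall inside a polygon
#'
#' Ray-casting with a half-open convention: points on a left/bottom boundary
#' are inside, on a right/top boundary outside, so tiling polygons partition
#' the plane.
#'
#' @param x,y point coordinates.
#' @param polygon two-column matrix of vertices (closed implicitly).
#' @return Logical vector.
#' @export
point_in_polygon <- function(x, y, polygon) {
  px <- polygon[, 1]; py <- polygon[, 2]
  n <- length(px)
  inside <- logical(length(x))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((py[i] > y) != (py[j] > y)) &
      (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside
}

# Mask raster values to cells whose centre lies in the polygon (NULL = keep
# all); returns the masked value matrix with outside cells set to NA.
clip_raster_values <- function(raster, polygon = NULL) {
  v <- raster$values
  if (is.null(polygon)) return(v)
  cc <- raster_cell_centers(raster)
  xs <- rep(cc$x, each = nrow(v))
  ys <- rep(cc$y, times = ncol(v))
  keep <- matrix(point_in_polygon(xs, ys, polygon), nrow = nrow(v))
  v[!keep] <- NA_integer_
  v
}
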