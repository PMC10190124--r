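#' Define a regular latitude/longitude grid
#'
#' A `grid_spec` describes a regular raster by the centre of its south-west
#' cell, the cell sizes, and the number of rows and columns. Row index
#' increases northward, column index eastward; all indices are 1-based.
#'
#' @param lat0,lon0 Centre coordinates (degrees) of the south-west cell.
#' @param dlat,dlon Cell sizes in degrees; must be positive.
#' @param nrows,ncols Grid dimensions.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(20, 100, 0.05, 0.05, 60, 60)
#' grid_lat(g)[1:3]
#' @export
grid_spec <- function(lat0, lon0, dlat, dlon, nrows, ncols) {
  stopifnot(dlat > 0, dlon > 0, nrows >= 1, ncols >= 1)
  structure(list(lat0 = lat0, lon0 = lon0, dlat = dlat, dlon = dlon,
                 nrows = as.integer(nrows), ncols = as.integer(ncols)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells, %.3f deg x %.3f deg, SW centre (%.3f, %.3f)\n",
              x$nrows, x$ncols, x$dlat, x$dlon, x$lat0, x$lon0))
  invisible(x)
}

#' @rdname grid_spec
#' @param grid A `grid_spec`.
#' @export
grid_lat <- function(grid) grid$lat0 + (seq_len(grid$nrows) - 1) * grid$dlat

#' @rdname grid_spec
#' @export
grid_lon <- function(grid) grid$lon0 + (seq_len(grid$ncols) - 1) * grid$dlon

#' Cell-centre coordinates of every cell
#'
#' @param grid A `grid_spec`.
#' @return A two-column matrix (lat, lon) with `nrows * ncols` rows in
#'   column-major (R matrix) order, matching `as.vector(field_matrix)`.
#' @export
grid_centres <- function(grid) {
  la <- grid_lat(grid); lo <- grid_lon(grid)
  cbind(lat = rep(la, times = grid$ncols), lon = rep(lo, each = grid$nrows))
}

#' Locate the grid cell containing a point
#'
#' Points are snapped to the nearest cell centre; points outside the grid
#' envelope (beyond half a cell from the outermost centres) return `NA`.
#'
#' @param grid A `grid_spec`.
#' @param lat,lon Point coordinates (degrees), recycled to common length.
#' @return A two-column integer matrix (row, col).
#' @export
grid_locate <- function(grid, lat, lon) {
  n <- max(length(lat), length(lon))
  lat <- rep_len(lat, n); lon <- rep_len(lon, n)
  i <- as.integer(round((lat - grid$lat0) / grid$dlat)) + 1L
  j <- as.integer(round((lon - grid$lon0) / grid$dlon)) + 1L
  i[i < 1L | i > grid$nrows] <- NA_integer_
  j[j < 1L | j > grid$ncols] <- NA_integer_
  cbind(row = i, col = j)
}
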