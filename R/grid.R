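#' Grid metadata for an island raster
#'
#' Describes a regular latitude/longitude grid in the WGS84 geographic
#' coordinate system. Coordinates refer to cell centres; row 1 is the
#' northernmost row and column 1 the westernmost column.
#'
#' @param n_rows,n_cols Grid dimensions (>= 1).
#' @param origin_lon,origin_lat Decimal-degree coordinates of the centre of
#'   the top-left (north-west) cell.
#' @param resolution Cell size in decimal degrees (> 0). The native product
#'   resolution is 0.0083 degrees (~1 km).
#' @param crs_id Coordinate reference system identifier; only the WGS84
#'   geographic identifier `"EPSG:4326"` is supported.
#' @return An object of class `grid_meta`.
#' @export
grid_meta <- function(n_rows, n_cols, origin_lon = 0, origin_lat = 0,
                      resolution = 0.0083, crs_id = "EPSG:4326") {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  stopifnot(length(n_rows) == 1L, length(n_cols) == 1L,
            n_rows >= 1L, n_cols >= 1L,
            is.numeric(resolution), length(resolution) == 1L, resolution > 0,
            is.numeric(origin_lon), is.numeric(origin_lat))
  if (!identical(crs_id, "EPSG:4326")) {
    stop("only the WGS84 geographic CRS ('EPSG:4326') is supported")
  }
  structure(
    list(n_rows = n_rows, n_cols = n_cols,
         origin_lon = as.numeric(origin_lon),
         origin_lat = as.numeric(origin_lat),
         resolution = as.numeric(resolution),
         crs_id = crs_id),
    class = "grid_meta")
}

#' @export
print.grid_meta <- function(x, ...) {
  cat(sprintf("<grid_meta> %d x %d cells, %.6g deg, origin (%.6g, %.6g), %s\n",
              x$n_rows, x$n_cols, x$resolution,
              x$origin_lon, x$origin_lat, x$crs_id))
  invisible(x)
}

#' Cell-centre coordinates of a grid
#'
#' @param grid A [grid_meta()] object.
#' @return A list with `lon` (length `n_cols`, ascending west to east) and
#'   `lat` (length `n_rows`, descending north to south).
#' @export
grid_coords <- function(grid) {
  stopifnot(inherits(grid, "grid_meta"))
  list(lon = grid$origin_lon + (seq_len(grid$n_cols) - 1) * grid$resolution,
       lat = grid$origin_lat - (seq_len(grid$n_rows) - 1) * grid$resolution)
}

grids_congruent <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$origin_lon - b$origin_lon) < tol &&
    abs(a$origin_lat - b$origin_lat) < tol &&
    abs(a$resolution - b$resolution) < tol
}

stop_if_incongruent <- function(a, b, what = "grids") {
  if (!grids_congruent(a, b)) stop(what, " are not congruent (shape/origin/resolution)")
  invisible(TRUE)
}
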