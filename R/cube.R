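# Domain containers: LST cubes, DEM grids, island scenes, gap-fill results.
# A cube stores values as an n_rows x n_cols x n_layers array of degrees
# Celsius with NA as the missing sentinel; layers are labelled YYYYMM.

#' YYYYMM layer label helpers
#'
#' Monthly layers are labelled by integer `YYYYMM` codes (e.g. `200101`),
#' the band-name convention of the published LST records.
#'
#' @param start_year First calendar year.
#' @param n_years Number of whole years.
#' @return `ym_seq()` returns an increasing integer vector of 12 * `n_years`
#'   labels; `ym_year()`/`ym_month()` split a label; `ym_shift()` shifts a
#'   label by a number of calendar months.
#' @examples
#' ym_seq(2001, 2)[1:3]     # 200101 200102 200103
#' ym_shift(200112, 1)      # 200201
#' @export
ym_seq <- function(start_year, n_years) {
  stopifnot(n_years >= 1)
  years <- rep(start_year + seq_len(n_years) - 1L, each = 12L)
  as.integer(years * 100L + rep(1:12, n_years))
}

#' @rdname ym_seq
#' @param ym Integer YYYYMM label(s).
#' @export
ym_year <- function(ym) ym %/% 100L

#' @rdname ym_seq
#' @export
ym_month <- function(ym) ym %% 100L

#' @rdname ym_seq
#' @param by Number of calendar months to shift by (may be negative).
#' @export
ym_shift <- function(ym, by) {
  m0 <- ym_year(ym) * 12L + (ym_month(ym) - 1L) + as.integer(by)
  as.integer((m0 %/% 12L) * 100L + (m0 %% 12L) + 1L)
}

check_ym_labels <- function(labels) {
  labels <- as.integer(labels)
  m <- ym_month(labels)
  if (any(m < 1L | m > 12L)) stop("unparseable YYYYMM layer label")
  if (length(labels) > 1L && any(diff(labels) <= 0L)) {
    stop("layer labels must be strictly increasing YYYYMM codes")
  }
  labels
}

#' Construct a monthly LST cube
#'
#' @param grid A [grid_meta()].
#' @param values Numeric array `n_rows x n_cols x n_layers` in degrees
#'   Celsius, with `NA` marking missing observations.
#' @param labels Integer `YYYYMM` layer labels, strictly increasing.
#' @param photoperiod `"Day"` or `"Night"` (the satellite overpass class).
#' @param land_mask Logical `n_rows x n_cols` matrix; sea cells (`FALSE`)
#'   are forced to missing in every layer.
#' @param physical_range Permitted value range in degrees C; non-missing
#'   values outside it are rejected.
#' @return An object of class `lst_cube`.
#' @export
lst_cube <- function(grid, values, labels, photoperiod = c("Day", "Night"),
                     land_mask = NULL, physical_range = c(-130, 70)) {
  photoperiod <- match.arg(photoperiod)
  stopifnot(inherits(grid, "grid_meta"))
  values <- as.array(values)
  if (length(dim(values)) == 2L) dim(values) <- c(dim(values), 1L)
  if (length(dim(values)) != 3L) stop("values must be a 3-d array")
  if (dim(values)[1] != grid$n_rows || dim(values)[2] != grid$n_cols) {
    stop("values shape does not match grid")
  }
  labels <- check_ym_labels(labels)
  if (dim(values)[3] != length(labels)) stop("one YYYYMM label per layer required")
  if (is.null(land_mask)) {
    land_mask <- matrix(TRUE, grid$n_rows, grid$n_cols)
  }
  stopifnot(is.logical(land_mask),
            all(dim(land_mask) == c(grid$n_rows, grid$n_cols)))
  storage.mode(values) <- "double"
  values[!land_mask] <- NA_real_  # sea is always missing, recycled over layers
  rng <- suppressWarnings(range(values, na.rm = TRUE))  # all-NA cube allowed
  if (is.finite(rng[1]) &&
      (rng[1] < physical_range[1] || rng[2] > physical_range[2])) {
    stop(sprintf("values outside physical range [%g, %g] degC",
                 physical_range[1], physical_range[2]))
  }
  structure(
    list(grid = grid, photoperiod = photoperiod, labels = labels,
         values = values, land_mask = land_mask),
    class = "lst_cube")
}

#' @export
print.lst_cube <- function(x, ...) {
  nl <- length(x$labels)
  land <- sum(x$land_mask)
  nobs <- sum(!is.na(x$values))
  cat(sprintf(
    "<lst_cube> %s, %d x %d cells (%d land), %d layers %d..%d, %.1f%% observed\n",
    x$photoperiod, x$grid$n_rows, x$grid$n_cols, land, nl,
    x$labels[1], x$labels[nl], 100 * nobs / (land * nl)))
  invisible(x)
}

n_layers <- function(cube) length(cube$labels)

#' Construct a DEM grid
#'
#' @param grid A [grid_meta()] congruent with the cubes it will be paired
#'   with.
#' @param elevation Numeric `n_rows x n_cols` matrix of elevations in
#'   metres. May be negative (sea floor) off-island.
#' @return An object of class `dem_grid`.
#' @export
dem_grid <- function(grid, elevation) {
  stopifnot(inherits(grid, "grid_meta"))
  elevation <- as.matrix(elevation)
  if (!all(dim(elevation) == c(grid$n_rows, grid$n_cols))) {
    stop("elevation shape does not match grid")
  }
  storage.mode(elevation) <- "double"
  structure(list(grid = grid, elevation = elevation), class = "dem_grid")
}

#' @export
print.dem_grid <- function(x, ...) {
  cat(sprintf("<dem_grid> %d x %d cells, elevation %.1f..%.1f m\n",
              x$grid$n_rows, x$grid$n_cols,
              min(x$elevation, na.rm = TRUE), max(x$elevation, na.rm = TRUE)))
  invisible(x)
}

#' Bundle the per-island inputs of the pipeline
#'
#' An island scene couples a DEM with congruent day and night LST cubes.
#' Scenes built by [simulate_scene()] additionally carry the fully-observed
#' truth cubes (`truth$day`, `truth$night`) for error computation.
#'
#' @param name Island name (used in output file names).
#' @param dem A [dem_grid()].
#' @param day,night [lst_cube()] objects sharing grid, land mask and labels.
#' @param truth Optional list of fully observed truth cubes.
#' @param provenance Free-text or list metadata (seeds, parameters).
#' @return An object of class `island_scene`.
#' @export
island_scene <- function(name, dem, day, night, truth = NULL,
                         provenance = list()) {
  stopifnot(inherits(dem, "dem_grid"), inherits(day, "lst_cube"),
            inherits(night, "lst_cube"))
  stop_if_incongruent(dem$grid, day$grid, "DEM and day cube")
  stop_if_incongruent(day$grid, night$grid, "day and night cubes")
  if (!identical(day$labels, night$labels)) {
    stop("day and night cubes must share layer labels")
  }
  if (!identical(day$land_mask, night$land_mask)) {
    stop("day and night cubes must share the land mask")
  }
  if (day$photoperiod != "Day" || night$photoperiod != "Night") {
    stop("photoperiods of the two cubes must be Day and Night")
  }
  structure(
    list(name = name, dem = dem, day = day, night = night,
         truth = truth, provenance = provenance),
    class = "island_scene")
}

#' @export
print.island_scene <- function(x, ...) {
  cat(sprintf("<island_scene> '%s'\n", x$name))
  print(x$dem); print(x$day); print(x$night)
  invisible(x)
}

# Replace the value array of a cube, keeping all metadata.
cube_with_values <- function(cube, values) {
  cube$values <- values
  cube
}

#' Linear indices of land cell-layers
#'
#' @param cube An [lst_cube()].
#' @param observed If `TRUE` restrict to non-missing entries, if `FALSE` to
#'   missing land entries, if `NA` return all land entries.
#' @return Integer vector of linear indices into the cube's value array.
#' @keywords internal
land_indices <- function(cube, observed = NA) {
  land3 <- array(cube$land_mask, dim = dim(cube$values))
  idx <- which(land3)
  if (is.na(observed)) return(idx)
  obs <- !is.na(cube$values[idx])
  if (observed) idx[obs] else idx[!obs]
}
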