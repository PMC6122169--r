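# MODIS-style conditioning: digital-number scaling, per-island quantile
# outlier exclusion, 8-day -> monthly aggregation, DEM resampling and
# missing-data accounting.

#' Scale MODIS digital numbers to degrees Celsius
#'
#' Applies the sensor conversion factor 0.02 (DN -> Kelvin) and subtracts
#' 273.15. DNs outside the product's valid range `[7500, 65535]` become
#' missing.
#'
#' @param raw_dn Integer digital numbers (vector, matrix or array).
#' @param valid_range Valid DN range.
#' @return Numeric object of the same shape, degC with `NA` for invalid.
#' @export
scale_to_celsius <- function(raw_dn, valid_range = c(7500, 65535)) {
  if (!is.numeric(raw_dn)) stop("raw_dn must be numeric (integer DNs)")
  finite <- raw_dn[!is.na(raw_dn)]
  if (any(finite != round(finite))) stop("raw_dn must be whole numbers")
  out <- raw_dn * 0.02 - 273.15
  out[!is.na(raw_dn) & (raw_dn < valid_range[1] | raw_dn > valid_range[2])] <- NA_real_
  out
}

#' Exclude observations outside a central empirical quantile interval
#'
#' Computes the island-wide empirical quantiles bounding a central mass
#' (default 99.99%, i.e. tails of 0.005% each) over all non-missing values
#' of the cube and sets values strictly outside them to missing. Quantiles
#' use linear interpolation of order statistics (type 7).
#'
#' @param cube An [lst_cube()] (or 8-day cube) with >= 2 non-missing
#'   values.
#' @param central_mass Central probability mass retained, in (0.5, 1].
#' @return List with `cube` (filtered) and `n_removed`.
#' @export
quantile_filter <- function(cube, central_mass = 0.9999) {
  stopifnot(is.numeric(central_mass), length(central_mass) == 1L)
  if (central_mass <= 0.5 || central_mass > 1) {
    stop("central_mass must be in (0.5, 1]")
  }
  vals <- cube$values
  obs <- vals[!is.na(vals)]
  if (length(obs) < 2) stop("cube must contain at least 2 non-missing values")
  a <- (1 - central_mass) / 2
  q <- stats::quantile(obs, c(a, 1 - a), type = 7, names = FALSE)
  drop_mask <- !is.na(vals) & (vals < q[1] | vals > q[2])
  vals[drop_mask] <- NA_real_
  list(cube = cube_with_values(cube, vals), n_removed = sum(drop_mask),
       bounds = q)
}

#' Average 8-day composites into monthly layers
#'
#' Each 8-day layer is assigned to the calendar month containing its
#' composite start date (no proration). Per cell and month, the mean of
#' the non-missing contributing values is taken; months with no
#' contributing value stay missing.
#'
#' @param values Numeric array `n_rows x n_cols x n_composites`.
#' @param dates `Date` vector of composite start dates, non-decreasing.
#' @param grid A [grid_meta()].
#' @param photoperiod `"Day"` or `"Night"`.
#' @param land_mask Optional land mask.
#' @return An [lst_cube()] with YYYYMM labels covering every month between
#'   the first and last composite month.
#' @export
monthly_mean <- function(values, dates, grid, photoperiod = c("Day", "Night"),
                         land_mask = NULL) {
  photoperiod <- match.arg(photoperiod)
  dates <- as.Date(dates)
  values <- as.array(values)
  stopifnot(length(dim(values)) == 3L, dim(values)[3] == length(dates))
  if (is.unsorted(dates)) stop("composite start dates must be ordered")
  ym <- as.integer(format(dates, "%Y%m"))
  first <- min(ym); last <- max(ym)
  m0 <- ym_year(first) * 12L + ym_month(first) - 1L
  m1 <- ym_year(last) * 12L + ym_month(last) - 1L
  labels <- vapply(m0:m1, function(m) (m %/% 12L) * 100L + (m %% 12L) + 1L,
                   integer(1))
  nr <- dim(values)[1]; nc <- dim(values)[2]
  out <- array(NA_real_, c(nr, nc, length(labels)))
  for (i in seq_along(labels)) {
    sel <- which(ym == labels[i])
    if (!length(sel)) next
    slab <- values[, , sel, drop = FALSE]
    cnt <- rowSums(!is.na(slab), dims = 2)
    s <- rowSums(slab, dims = 2, na.rm = TRUE)
    out[, , i] <- ifelse(cnt > 0, s / cnt, NA_real_)
  }
  lst_cube(grid, out, labels, photoperiod, land_mask)
}

#' Bilinearly resample a DEM to a target grid
#'
#' Each target cell centre's value is the bilinear interpolation of the
#' four surrounding source cell centres. The target extent must lie inside
#' the source's cell-centre extent.
#'
#' @param dem_fine Source [dem_grid()].
#' @param target Target [grid_meta()].
#' @return A [dem_grid()] on the target grid.
#' @export
resample_bilinear <- function(dem_fine, target) {
  stopifnot(inherits(dem_fine, "dem_grid"), inherits(target, "grid_meta"))
  src <- dem_fine$grid
  sc <- grid_coords(src)
  tc <- grid_coords(target)
  eps <- 1e-9
  if (min(tc$lon) < min(sc$lon) - eps || max(tc$lon) > max(sc$lon) + eps ||
      min(tc$lat) < min(sc$lat) - eps || max(tc$lat) > max(sc$lat) + eps) {
    stop("target grid extends outside source DEM coverage")
  }
  # fractional index of each target coordinate in the source axes
  fx <- (tc$lon - sc$lon[1]) / src$resolution + 1      # col axis, ascending
  fy <- (sc$lat[1] - tc$lat) / src$resolution + 1      # row axis, descending
  clampi <- function(f, n) pmin(pmax(floor(f), 1), n - 1)
  ix <- clampi(fx, src$n_cols); wx <- fx - ix
  iy <- clampi(fy, src$n_rows); wy <- fy - iy
  E <- dem_fine$elevation
  out <- matrix(NA_real_, target$n_rows, target$n_cols)
  for (i in seq_len(target$n_rows)) {
    r0 <- iy[i]; a <- wy[i]
    top <- E[r0, ix] * (1 - wx) + E[r0, ix + 1] * wx
    bot <- E[r0 + 1, ix] * (1 - wx) + E[r0 + 1, ix + 1] * wx
    out[i, ] <- top * (1 - a) + bot * a
  }
  dem_grid(target, out)
}

#' Per-cell missing counts and overall availability
#'
#' @param cube An [lst_cube()].
#' @return List with `counts` (matrix of per-land-cell missing counts, `NA`
#'   at sea), `pct_available` (overall percent of land cell-layers
#'   observed), `n_layers`.
#' @export
missing_profile <- function(cube) {
  stopifnot(inherits(cube, "lst_cube"))
  nl <- n_layers(cube)
  counts <- rowSums(is.na(cube$values), dims = 2)
  counts[!cube$land_mask] <- NA_real_
  land_total <- sum(cube$land_mask) * nl
  n_missing <- sum(counts, na.rm = TRUE)
  list(counts = counts,
       pct_available = 100 * (land_total - n_missing) / land_total,
       n_layers = nl)
}

#' Is a cube eligible for gap-filling?
#'
#' Islands with more than `threshold` percent missing land cell-layers
#' across the record are not gap-filled. The boundary (exactly the
#' threshold missing) is eligible.
#'
#' @param cube An [lst_cube()].
#' @param threshold Maximum tolerated missing percentage.
#' @return `TRUE` if the missing fraction is <= `threshold` percent.
#' @export
eligible_for_gapfill <- function(cube, threshold = 50) {
  prof <- missing_profile(cube)
  (100 - prof$pct_available) <= threshold
}
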