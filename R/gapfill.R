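# The elevation-aware spatio-temporal quantile-regression gap-filler.
#
# For every missing land cell-layer a spatio-temporal subset is extracted
# (an 11x11 cell window crossed with the previous/same/next month in the
# previous/current/next two years: up to 121 cells x 15 slices = 1815
# entries, 1814 potential supporting observations). A linear quantile
# regression of value ~ slice anomaly + elevation, fitted by pinball-loss
# minimization, predicts the target at an empirically estimated quantile
# level tau*, with 95% confidence limits from fits at tau = 0.025/0.975.
# Point predictions (only) are clipped to the island's observed range.

#' Spatio-temporal search-strategy parameters
#'
#' @param spatial_radius Cells searched in every spatial direction
#'   (default 5, i.e. an 11x11 window centred on the target).
#' @param month_offsets Month-of-year offsets included (default previous,
#'   same and next month).
#' @param year_offsets Year offsets included (default the previous and
#'   next two-year period plus the current year).
#' @param n_min Minimum support (observed subset entries) required to fit;
#'   below it the prediction fails. Must exceed the coefficient count.
#' @param tau_ci Quantile levels of the lower/upper confidence limits.
#' @param clip_range Optional fixed `c(min, max)` clip range in degC;
#'   `NULL` means compute it from the cube being filled.
#' @param predict_at `"tau_star"` (default) predicts at the target cell's
#'   estimated quantile level; `"median"` predicts at tau = 0.5.
#' @return A list of class `subset_spec`.
#' @export
subset_spec <- function(spatial_radius = 5L, month_offsets = -1:1,
                        year_offsets = -2:2, n_min = 10L,
                        tau_ci = c(0.025, 0.975), clip_range = NULL,
                        predict_at = c("tau_star", "median")) {
  predict_at <- match.arg(predict_at)
  stopifnot(spatial_radius >= 1, n_min >= 4,
            all(tau_ci > 0), all(tau_ci < 1), tau_ci[1] < tau_ci[2])
  if (!is.null(clip_range)) {
    stopifnot(length(clip_range) == 2, clip_range[1] <= clip_range[2])
  }
  structure(
    list(spatial_radius = as.integer(spatial_radius),
         month_offsets = as.integer(sort(unique(month_offsets))),
         year_offsets = as.integer(sort(unique(year_offsets))),
         n_min = as.integer(n_min), tau_ci = tau_ci,
         clip_range = clip_range, predict_at = predict_at),
    class = "subset_spec")
}

#' Clip range of a cube
#'
#' The island's minimum and maximum observed temperatures, which bound
#' gap-fill point predictions (confidence intervals are never clipped).
#'
#' @param cube An [lst_cube()] with at least one non-missing value.
#' @return Numeric `c(min, max)` in degC.
#' @export
compute_clip_range <- function(cube) {
  v <- cube$values[!is.na(cube$values)]
  if (!length(v)) stop("cannot compute a clip range from an all-missing cube")
  range(v)
}

#' Clamp a point prediction into the clip range
#'
#' @param value Numeric value(s).
#' @param clip_range `c(min, max)`.
#' @return Clamped value(s). Confidence limits must not be passed here.
#' @export
clip_mean <- function(value, clip_range) {
  stopifnot(length(clip_range) == 2, clip_range[1] <= clip_range[2])
  pmin(pmax(value, clip_range[1]), clip_range[2])
}

# Indices (into cube$labels) of the subset's time slices for a target
# layer, in ascending label order. Month offsets cross year boundaries;
# slices falling outside the record are dropped.
subset_slices <- function(labels, target_layer, spec) {
  lab <- labels[target_layer]
  want <- sort(unique(as.integer(outer(spec$year_offsets * 12L,
                                       spec$month_offsets, "+"))))
  cand <- ym_shift(lab, want)
  idx <- match(cand, labels)
  sort(unique(idx[!is.na(idx)]))
}

#' Extract the spatio-temporal subset around a target cell-layer
#'
#' @param cube An [lst_cube()].
#' @param dem A congruent [dem_grid()].
#' @param cell Integer `c(row, col)` of the target land cell.
#' @param layer Target layer index or YYYYMM label.
#' @param spec A [subset_spec()].
#' @return A list of class `st_subset`: `values` (window cells x slices
#'   with the target entry forced missing), `elev`, `slice_labels`,
#'   `target_cell`/`target_slice` (indices into the subset), and the
#'   window's row/col index vectors.
#' @export
extract_subset <- function(cube, dem, cell, layer, spec = subset_spec()) {
  stopifnot(inherits(cube, "lst_cube"), inherits(dem, "dem_grid"))
  stop_if_incongruent(cube$grid, dem$grid, "cube and DEM")
  if (length(layer) != 1) stop("one target layer required")
  if (layer > 10000L) {                   # given as YYYYMM label
    layer <- match(as.integer(layer), cube$labels)
    if (is.na(layer)) stop("layer label absent from cube")
  }
  stopifnot(layer >= 1, layer <= n_layers(cube))
  r <- cell[1]; cl <- cell[2]
  stopifnot(r >= 1, r <= cube$grid$n_rows, cl >= 1, cl <= cube$grid$n_cols)
  R <- spec$spatial_radius
  rows <- max(1L, r - R):min(cube$grid$n_rows, r + R)
  cols <- max(1L, cl - R):min(cube$grid$n_cols, cl + R)
  slices <- subset_slices(cube$labels, layer, spec)
  vals <- cube$values[rows, cols, slices, drop = FALSE]
  n_cells <- length(rows) * length(cols)
  dim(vals) <- c(n_cells, length(slices))
  target_cell <- match(r, rows) + (match(cl, cols) - 1L) * length(rows)
  target_slice <- match(layer, slices)
  vals[target_cell, target_slice] <- NA_real_
  structure(
    list(values = vals,
         elev = as.vector(dem$elevation[rows, cols]),
         slice_labels = cube$labels[slices],
         target_cell = target_cell, target_slice = target_slice,
         rows = rows, cols = cols),
    class = "st_subset")
}

#' Support of a subset
#'
#' The number of observed entries in the spatio-temporal subset, excluding
#' the target entry itself.
#'
#' @param subset An `st_subset` from [extract_subset()].
#' @return Integer count.
#' @export
count_support <- function(subset) {
  sum(!is.na(subset$values))
}

#' Estimate the target cell's quantile level
#'
#' In every slice where the target cell is observed, the target's
#' normalized mid-rank (Hazen position, `(rank - 0.5) / n`) among that
#' slice's observed cells is computed; tau* is their mean, truncated to
#' `[0.05, 0.95]`. If the target cell is observed in no slice, tau* falls
#' back to 0.5 (the median).
#'
#' @param subset An `st_subset`.
#' @return Quantile level tau* in `[0.05, 0.95]`.
#' @export
estimate_target_quantile <- function(subset) {
  taus <- numeric(0)
  for (s in seq_along(subset$slice_labels)) {
    y <- subset$values[, s]
    ty <- y[subset$target_cell]
    if (is.na(ty)) next
    obs <- y[!is.na(y)]
    r <- rank(obs, ties.method = "average")[match(ty, obs)]
    taus <- c(taus, (r - 0.5) / length(obs))
  }
  if (!length(taus)) return(0.5)
  min(max(mean(taus), 0.05), 0.95)
}

#' Predict a missing value from a subset by quantile regression
#'
#' Fits `value ~ slice_anomaly + elevation` by pinball-loss minimization,
#' where a slice's anomaly is its observed mean minus the subset's grand
#' observed mean (0 for slices without observations). The point prediction
#' evaluates the tau* fit at the target's covariates; the confidence
#' limits evaluate fits at the `tau_ci` levels. Collinear terms (constant
#' elevation, single informative slice) are dropped. The three predictions
#' are sorted so `lower <= mean <= upper` (monotone rearrangement of
#' crossing quantile planes).
#'
#' @param subset An `st_subset`.
#' @param tau_star Target quantile level, e.g. from
#'   [estimate_target_quantile()].
#' @param spec A [subset_spec()].
#' @return List with `failed` flag and, when successful, `mean`, `lower`,
#'   `upper` (degC, unclipped) plus `support` and `tau_star`.
#' @export
qr_predict <- function(subset, tau_star = 0.5, spec = subset_spec()) {
  support <- count_support(subset)
  if (support < spec$n_min) {
    return(list(failed = TRUE, support = support))
  }
  vals <- subset$values
  n_cells <- nrow(vals); n_slices <- ncol(vals)
  obs_idx <- which(!is.na(vals))
  y <- vals[obs_idx]
  slice_of <- (obs_idx - 1L) %/% n_cells + 1L
  cell_of <- (obs_idx - 1L) %% n_cells + 1L
  grand <- mean(y)
  slice_mean <- vapply(seq_len(n_slices), function(s) {
    v <- vals[, s]; v <- v[!is.na(v)]
    if (length(v)) mean(v) - grand else 0
  }, numeric(1))
  anom <- slice_mean[slice_of]
  elev <- subset$elev[cell_of]
  X <- cbind(intercept = 1, anom = anom, elev = elev)
  x0 <- c(1, slice_mean[subset$target_slice], subset$elev[subset$target_cell])
  keep <- c(TRUE, stats::sd(anom) > 1e-9, stats::sd(elev) > 1e-9)
  X <- X[, keep, drop = FALSE]
  x0 <- x0[keep]
  while (ncol(X) > 1 && qr(X)$rank < ncol(X)) {   # residual collinearity
    X <- X[, -ncol(X), drop = FALSE]
    x0 <- x0[-length(x0)]
  }
  tau_mean <- if (spec$predict_at == "median") 0.5 else tau_star
  pred <- numeric(3)
  basis <- NULL                       # warm-start successive tau fits
  taus <- c(spec$tau_ci[1], tau_mean, spec$tau_ci[2])
  for (i in seq_along(taus)) {
    fit <- rq_fit(X, y, taus[i], basis0 = basis)
    basis <- fit$basis
    pred[i] <- sum(x0 * fit$coefficients)
  }
  pred <- sort(pred)
  list(failed = FALSE, mean = pred[2], lower = pred[1], upper = pred[3],
       support = support, tau_star = tau_mean)
}

#' Gap-fill a cube
#'
#' Attempts every missing land cell-layer of an eligible cube (<= 50%
#' missing). Observed values pass through unchanged; filled means are
#' clipped to the island clip range; confidence limits are stored
#' unclipped and only for filled cells; predictions whose support is below
#' `spec$n_min` are flagged failed and stay missing.
#'
#' @param cube An [lst_cube()].
#' @param dem A congruent [dem_grid()].
#' @param spec A [subset_spec()].
#' @param max_missing_pct Eligibility threshold (percent missing).
#' @return An object of class `gapfill_result`: cubes `mean`, `lower_ci`,
#'   `upper_ci`, `obs`, logical `failed` array, `clip_range`, `support`
#'   array and counts `n_filled`, `n_failed`.
#' @export
gapfill_cube <- function(cube, dem, spec = subset_spec(),
                         max_missing_pct = 50) {
  stopifnot(inherits(cube, "lst_cube"), inherits(dem, "dem_grid"))
  stop_if_incongruent(cube$grid, dem$grid, "cube and DEM")
  if (!eligible_for_gapfill(cube, max_missing_pct)) {
    stop(sprintf(
      "cube is ineligible for gap-filling (more than %g%% of land cell-layers missing)",
      max_missing_pct))
  }
  clip <- if (is.null(spec$clip_range)) compute_clip_range(cube) else spec$clip_range
  dims <- dim(cube$values)
  mean_vals <- cube$values
  lower <- array(NA_real_, dims)
  upper <- array(NA_real_, dims)
  failed <- array(FALSE, dims)
  support <- array(NA_integer_, dims)
  targets <- land_indices(cube, observed = FALSE)
  if (length(targets)) {
    tpos <- arrayInd(targets, dims)
    # group targets by layer: the slice set is shared within a layer
    for (l in unique(tpos[, 3])) {
      sel <- which(tpos[, 3] == l)
      for (i in sel) {
        sub <- extract_subset(cube, dem, tpos[i, 1:2], l, spec)
        tau_star <- estimate_target_quantile(sub)
        pr <- qr_predict(sub, tau_star, spec)
        idx <- targets[i]
        support[idx] <- pr$support
        if (pr$failed) {
          failed[idx] <- TRUE
        } else {
          mean_vals[idx] <- clip_mean(pr$mean, clip)
          lower[idx] <- pr$lower
          upper[idx] <- pr$upper
        }
      }
    }
  }
  structure(
    list(mean = cube_with_values(cube, mean_vals),
         lower_ci = cube_with_values(cube, lower),
         upper_ci = cube_with_values(cube, upper),
         obs = cube,
         failed = failed, support = support, clip_range = clip,
         n_filled = length(targets) - sum(failed),
         n_failed = sum(failed)),
    class = "gapfill_result")
}

#' @export
print.gapfill_result <- function(x, ...) {
  cat(sprintf(
    "<gapfill_result> %s: %d gaps attempted, %d filled, %d failed; clip range [%.2f, %.2f] degC\n",
    x$obs$photoperiod, x$n_filled + x$n_failed, x$n_filled, x$n_failed,
    x$clip_range[1], x$clip_range[2]))
  invisible(x)
}

#' Climatological month-mean baseline imputer
#'
#' Fills each missing land cell-layer with the cell's mean over observed
#' values of the same calendar month; used as the reference imputer the
#' quantile-regression gap-filler must beat.
#'
#' @param cube An [lst_cube()].
#' @return A cube with gaps filled where the cell has at least one
#'   observation of that calendar month.
#' @export
impute_climatology <- function(cube) {
  months <- ym_month(cube$labels)
  vals <- cube$values
  for (m in unique(months)) {
    sel <- which(months == m)
    slab <- cube$values[, , sel, drop = FALSE]
    cnt <- rowSums(!is.na(slab), dims = 2)
    clim <- ifelse(cnt > 0, rowSums(slab, dims = 2, na.rm = TRUE) / cnt,
                   NA_real_)
    for (t in sel) {
      miss <- is.na(vals[, , t]) & cube$land_mask & cnt > 0
      layer <- vals[, , t]
      layer[miss] <- clim[miss]
      vals[, , t] <- layer
    }
  }
  cube_with_values(cube, vals)
}
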