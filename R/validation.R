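# Technical-validation machinery: knockout scenarios, error statistics,
# support-error quantile regression, Moran's I, and the missingness /
# error-frequency GLM diagnostics.

#' Randomly delete observed cells from a cube (point knockout)
#'
#' Deletes exactly `round(fraction * n_observed)` observed land
#' cell-layers, drawn uniformly without replacement.
#'
#' @param cube An [lst_cube()].
#' @param fraction Fraction of observed entries to delete, in (0, 1).
#' @param seed Integer seed (deterministic deletions).
#' @return A list of class `knockout_result`: `cube` (thinned), `deleted`
#'   (linear indices), `truth` (the deleted values), `achieved_fraction`,
#'   `mode`, `seed`.
#' @export
knockout_random <- function(cube, fraction, seed = 1L) {
  stopifnot(inherits(cube, "lst_cube"), fraction > 0, fraction < 1)
  obs <- land_indices(cube, observed = TRUE)
  n_del <- round(fraction * length(obs))
  del <- with_seed(seed, sample(obs, n_del))
  vals <- cube$values
  truth <- vals[del]
  vals[del] <- NA_real_
  structure(
    list(cube = cube_with_values(cube, vals), deleted = del, truth = truth,
         achieved_fraction = n_del / length(obs), mode = "random",
         seed = as.integer(seed)),
    class = "knockout_result")
}

#' Delete observed cells in random 3x3 spatial clusters
#'
#' Repeatedly draws a random land cell-layer centre and deletes the 3x3
#' spatial block around it in that layer (truncated at grid edges;
#' already-missing cells count once), until the achieved deleted fraction
#' reaches the target. The final fraction may overshoot by at most one
#' block (9 / n_observed).
#'
#' @inheritParams knockout_random
#' @return A `knockout_result` (see [knockout_random()]).
#' @export
knockout_clustered <- function(cube, fraction, seed = 1L) {
  stopifnot(inherits(cube, "lst_cube"), fraction > 0, fraction < 1)
  nr <- cube$grid$n_rows; nc <- cube$grid$n_cols
  obs <- land_indices(cube, observed = TRUE)
  n_obs <- length(obs)
  target <- fraction * n_obs
  vals <- cube$values
  land3 <- array(cube$land_mask, dim = dim(vals))
  deleted <- logical(length(vals))
  n_del <- 0L
  with_seed(seed, {
    centres <- land_indices(cube, observed = NA)
    guard <- 0L
    while (n_del < target) {
      guard <- guard + 1L
      if (guard > 100L * n_obs) stop("knockout fraction unreachable")
      ctr <- arrayInd(sample(centres, 1L), dim(vals))
      rows <- max(1L, ctr[1] - 1L):min(nr, ctr[1] + 1L)
      cols <- max(1L, ctr[2] - 1L):min(nc, ctr[2] + 1L)
      block <- as.vector(outer(rows, (cols - 1L) * nr, "+")) +
        (ctr[3] - 1L) * nr * nc
      new <- block[!deleted[block] & !is.na(vals[block]) & land3[block]]
      if (length(new)) {
        deleted[new] <- TRUE
        n_del <- n_del + length(new)
      }
    }
  })
  del <- which(deleted)
  truth <- vals[del]
  vals[del] <- NA_real_
  structure(
    list(cube = cube_with_values(cube, vals), deleted = del, truth = truth,
         achieved_fraction = n_del / n_obs, mode = "clustered",
         seed = as.integer(seed)),
    class = "knockout_result")
}

#' Error statistics of gap-fill predictions against withheld truth
#'
#' Errors follow the convention `error = observed - predicted`, so a
#' negative mean error means predictions run warmer than observations.
#'
#' @param predicted Numeric predictions (NA where the fill failed).
#' @param truth Numeric withheld observations, same length.
#' @return A list of class `error_stats`: `rmse`, `mean_error`,
#'   `error_range` (max - min), `error_sd` (sample SD), `n`, `n_failed`.
#' @export
error_stats <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  ok <- !is.na(predicted) & !is.na(truth)
  n_failed <- sum(is.na(predicted) & !is.na(truth))
  e <- truth[ok] - predicted[ok]
  if (!length(e)) stop("no successfully predicted deletions to score")
  structure(
    list(rmse = sqrt(mean(e^2)), mean_error = mean(e),
         error_range = max(e) - min(e),
         error_sd = if (length(e) > 1) stats::sd(e) else 0,
         n = length(e), n_failed = n_failed),
    class = "error_stats")
}

#' @export
print.error_stats <- function(x, ...) {
  cat(sprintf(
    "<error_stats> n=%d rmse=%.3f mean=%.3f range=%.3f sd=%.3f failed=%d\n",
    x$n, x$rmse, x$mean_error, x$error_range, x$error_sd, x$n_failed))
  invisible(x)
}

#' Median quantile regression of absolute error on support
#'
#' Fits `|error| = a + b * support` at the median (tau = 0.5) by
#' pinball-loss minimization. Goodness of fit is the Koenker-Machado R1
#' (one minus the ratio of tau-weighted absolute-residual sums of the full
#' and the intercept-only fits). The slope's standard error comes from a
#' seeded case-resampling bootstrap (B = 200); t and its two-sided p use
#' n - 2 residual degrees of freedom.
#'
#' @param abs_errors Non-negative absolute prediction errors.
#' @param supports Non-negative integer support counts, same length.
#' @param n_boot Bootstrap replicates for the slope SE.
#' @param seed Bootstrap seed.
#' @return A list of class `support_error_fit` with `intercept`, `slope`,
#'   `slope_se`, `t`, `p`, `pseudo_r2`, `n`, `mean_support`,
#'   `min_support`.
#' @export
support_error_qr <- function(abs_errors, supports, n_boot = 200L, seed = 1L) {
  ok <- !is.na(abs_errors) & !is.na(supports)
  y <- abs_errors[ok]; s <- supports[ok]
  n <- length(y)
  if (n < 10) stop("need at least 10 error/support pairs")
  if (stats::sd(s) == 0) stop("supports are constant; slope undefined")
  X <- cbind(1, s)
  fit <- rq_fit(X, y, 0.5)
  fit$coefficients <- unname(fit$coefficients)
  slope <- fit$coefficients[2]
  r2 <- rq_pseudo_r2(fit, X, y)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      if (stats::sd(s[i]) == 0) return(NA_real_)
      rq_fit(cbind(1, s[i]), y[i], 0.5)$coefficients[2]
    }, numeric(1))
  })
  se <- stats::sd(boots, na.rm = TRUE)
  tval <- slope / se
  structure(
    list(intercept = fit$coefficients[1], slope = slope, slope_se = se,
         t = tval, p = 2 * stats::pt(-abs(tval), df = n - 2),
         pseudo_r2 = r2, n = n, mean_support = mean(s),
         min_support = min(s)),
    class = "support_error_fit")
}

#' @export
print.support_error_fit <- function(x, ...) {
  cat(sprintf(
    "<support_error_fit> n=%d slope=%.2g (SE %.2g) t=%.2f p=%.3g pseudo-R2=%.3f mean support=%.1f min=%d\n",
    x$n, x$slope, x$slope_se, x$t, x$p, x$pseudo_r2, x$mean_support,
    as.integer(x$min_support)))
  invisible(x)
}

# Queen-contiguity edge list (i, j) over the non-missing cells of a grid
# statistic, with row-standardized weights w_ij = 1 / degree(i).
queen_edges <- function(mat) {
  nr <- nrow(mat); nc <- ncol(mat)
  keep <- !is.na(mat)
  id <- matrix(NA_integer_, nr, nc)
  id[keep] <- seq_len(sum(keep))
  shifts <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                 c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  from <- integer(0); to <- integer(0)
  for (s in shifts) {
    r_src <- seq_len(nr); c_src <- seq_len(nc)
    r_ok <- r_src + s[1] >= 1 & r_src + s[1] <= nr
    c_ok <- c_src + s[2] >= 1 & c_src + s[2] <= nc
    rs <- r_src[r_ok]; cs <- c_src[c_ok]
    a <- id[rs, cs, drop = FALSE]
    b <- id[rs + s[1], cs + s[2], drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    from <- c(from, a[ok]); to <- c(to, b[ok])
  }
  list(from = from, to = to, n = sum(keep), id = id)
}

#' Global Moran's I with queen contiguity
#'
#' `I = (n / W) * sum_ij w_ij z_i z_j / sum_i z_i^2` with centred values
#' z, queen-contiguity weights (default row-standardized) and
#' `W = sum w_ij`. Expectation, variance and the two-sided p-value follow
#' the normality assumption.
#'
#' @param values Numeric matrix of the per-cell statistic; `NA` cells
#'   (e.g. sea) are excluded from the neighbourhood graph.
#' @param row_standardize Row-standardize the weights (default) or use
#'   binary weights.
#' @return A list of class `morans_test`: `I`, `expected_I`, `variance`,
#'   `z`, `p`, `n`.
#' @export
morans_i <- function(values, row_standardize = TRUE) {
  stopifnot(is.matrix(values))
  g <- queen_edges(values)
  n <- g$n
  if (n < 9) stop("need at least 9 non-missing cells")
  x <- values[!is.na(values)]   # column-major, matching the id assignment
  if (stats::sd(x) == 0) stop("constant field: Moran's I undefined")
  z <- x - mean(x)
  deg <- tabulate(g$from, nbins = n)
  w <- if (row_standardize) 1 / deg[g$from] else rep(1, length(g$from))
  W <- sum(w)
  num <- sum(w * z[g$from] * z[g$to])
  I <- (n / W) * num / sum(z^2)
  EI <- -1 / (n - 1)
  # variance under normality (Cliff & Ord): needs S1, S2
  # S1 = 1/2 sum_ij (w_ij + w_ji)^2 ; S2 = sum_i (w_i. + w_.i)^2
  key <- paste(pmin(g$from, g$to), pmax(g$from, g$to))
  wv <- w
  # sum w_ij + w_ji per unordered pair: edges appear once per direction
  pair_sum <- tapply(wv, key, sum)
  S1 <- 0.5 * sum(pair_sum^2)
  w_out <- tapply(wv, g$from, sum)
  w_in <- tapply(wv, g$to, sum)
  all_ids <- as.character(seq_len(n))
  S2 <- sum((unname(w_out[all_ids]) %na0% 0 + unname(w_in[all_ids]) %na0% 0)^2)
  VI <- (n^2 * S1 - n * S2 + 3 * W^2) / (W^2 * (n^2 - 1)) - EI^2
  zscore <- (I - EI) / sqrt(VI)
  structure(
    list(I = I, expected_I = EI, variance = VI, z = zscore,
         p = 2 * stats::pnorm(-abs(zscore)), n = n),
    class = "morans_test")
}

`%na0%` <- function(a, b) { a[is.na(a)] <- b; a }

#' @export
print.morans_test <- function(x, ...) {
  cat(sprintf("<morans_test> I=%.4f E[I]=%.4f var=%.3g z=%.2f p=%.3g (n=%d)\n",
              x$I, x$expected_I, x$variance, x$z, x$p, x$n))
  invisible(x)
}

#' Binomial logit GLM of missingness on spatio-temporal factors
#'
#' Models `is_missing` (1 = missing, 0 = observed) on photoperiod, season
#' and elevation with a logit link, by maximum likelihood.
#'
#' @param table Data frame with columns `is_missing` (0/1), `photoperiod`,
#'   `season` (factors or character) and `elevation` (metres).
#' @return A list of class `missingness_fit` with `coefficients` data
#'   frame (`estimate`, `se`, `z`, `p`), the fitted `glm` object, and a
#'   `separation` flag.
#' @export
missingness_glm <- function(table) {
  need <- c("is_missing", "photoperiod", "season", "elevation")
  stopifnot(all(need %in% names(table)))
  y <- table$is_missing
  if (length(unique(y)) < 2) stop("both outcome classes must be present")
  fit <- stats::glm(is_missing ~ photoperiod + season + elevation,
                    family = stats::binomial("logit"), data = table,
                    control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  co <- summary(fit)$coefficients
  separation <- !fit$converged || any(abs(co[, 1]) > 15 & co[, 2] > 50)
  if (separation) warning("possible complete separation in missingness GLM")
  structure(
    list(coefficients = data.frame(term = rownames(co), estimate = co[, 1],
                                   se = co[, 2], z = co[, 3], p = co[, 4],
                                   row.names = NULL),
         model = fit, separation = separation),
    class = "missingness_fit")
}

#' Negative-binomial GLM of error frequency on photoperiod and elevation
#'
#' Models per-cell counts of gap-fill errors exceeding a threshold (the
#' caller applies the threshold, conventionally 1 degC) with a log link
#' and maximum-likelihood dispersion.
#'
#' @param table Data frame with columns `count` (non-negative integers),
#'   `photoperiod` and `elevation`.
#' @return A list of class `error_freq_fit` with a `coefficients` data
#'   frame, `theta` (ML dispersion), and the fitted model.
#' @export
error_freq_glm <- function(table) {
  need <- c("count", "photoperiod", "elevation")
  stopifnot(all(need %in% names(table)))
  if (all(table$count == 0)) stop("all counts are zero")
  form <- if (length(unique(table$photoperiod)) > 1) {
    count ~ photoperiod + elevation
  } else {
    count ~ elevation
  }
  fit <- suppressWarnings(MASS::glm.nb(form, data = table))
  co <- summary(fit)$coefficients
  structure(
    list(coefficients = data.frame(term = rownames(co), estimate = co[, 1],
                                   se = co[, 2], z = co[, 3], p = co[, 4],
                                   row.names = NULL),
         theta = fit$theta, model = fit),
    class = "error_freq_fit")
}

#' Run the knockout validation suite on a scene
#'
#' For each photoperiod and deletion fraction: knock out observed cells
#' (points or 3x3 clusters), gap-fill the thinned cube, and score the
#' predictions against the withheld values. In clustered mode the
#' support-error median quantile regression is additionally fitted.
#'
#' @param scene An [island_scene()].
#' @param mode `"random"` or `"clustered"` deletions.
#' @param fractions Deletion fractions (the canonical six scenarios).
#' @param spec A [subset_spec()].
#' @param seed Integer seed; each scenario derives its own sub-seed.
#' @param photoperiods Which cubes to validate.
#' @return A list of class `validation_report`: `errors` (a Table-2-shaped
#'   data frame), `support_fits` (Table-3-shaped data frame, clustered
#'   mode), and `details` (per-scenario deleted indices, errors,
#'   supports).
#' @export
run_validation_suite <- function(scene, mode = c("random", "clustered"),
                                 fractions = c(0.05, 0.10, 0.20, 0.30, 0.40, 0.50),
                                 spec = subset_spec(), seed = 1L,
                                 photoperiods = c("Day", "Night")) {
  mode <- match.arg(mode)
  stopifnot(inherits(scene, "island_scene"))
  knock_fun <- if (mode == "random") knockout_random else knockout_clustered
  err_rows <- list(); fit_rows <- list(); details <- list()
  for (pp in photoperiods) {
    cube <- if (pp == "Day") scene$day else scene$night
    prof <- missing_profile(cube)
    if (100 - prof$pct_available > 10) {
      warning(sprintf(
        "%s cube has %.1f%% missing observations; knockout validation is intended for cubes with < 10%% missing",
        pp, 100 - prof$pct_available))
    }
    for (k in seq_along(fractions)) {
      f <- fractions[k]
      sc_seed <- seed + 1000L * k + (if (pp == "Day") 0L else 500L)
      ko <- knock_fun(cube, f, seed = sc_seed)
      # heavy knockouts may push the cube past the production eligibility
      # threshold; the exclusion rule does not apply to validation runs
      res <- gapfill_cube(ko$cube, scene$dem, spec, max_missing_pct = 100)
      pred <- res$mean$values[ko$deleted]
      pred[res$failed[ko$deleted]] <- NA_real_
      st <- error_stats(pred, ko$truth)
      err_rows[[length(err_rows) + 1L]] <- data.frame(
        photoperiod = pp, fraction = f, rmse = st$rmse,
        mean_error = st$mean_error, error_range = st$error_range,
        error_sd = st$error_sd, n = st$n, n_failed = st$n_failed,
        achieved_fraction = ko$achieved_fraction)
      det <- list(photoperiod = pp, fraction = f, deleted = ko$deleted,
                  errors = ko$truth - pred,
                  supports = res$support[ko$deleted])
      if (mode == "clustered") {
        sf <- support_error_qr(abs(det$errors), det$supports,
                               seed = sc_seed)
        fit_rows[[length(fit_rows) + 1L]] <- data.frame(
          photoperiod = pp, fraction = f, mean_support = sf$mean_support,
          min_support = sf$min_support, slope = sf$slope,
          slope_se = sf$slope_se, pseudo_r2 = sf$pseudo_r2, t = sf$t,
          resid_df = sf$n - 2, p = sf$p)
      }
      details[[length(details) + 1L]] <- det
    }
  }
  structure(
    list(errors = do.call(rbind, err_rows),
         support_fits = if (length(fit_rows)) do.call(rbind, fit_rows),
         details = details, mode = mode, seed = as.integer(seed)),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s knockout, %d scenarios\n",
              x$mode, nrow(x$errors)))
  print(x$errors, digits = 3)
  invisible(x)
}
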