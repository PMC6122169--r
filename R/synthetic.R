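# Synthetic island scenes.
#
# The generator emulates the statistical structure of a sub-Antarctic
# island LST record: a single volcanic peak with a steep elevational
# gradient, a seasonal temperature cycle, a linear lapse with elevation, a
# windward/leeward (west-east) thermal asymmetry, month-slice anomalies,
# pixel noise, and cloud-gap missingness that is spatially autocorrelated
# and more probable at high elevation, by day, and in austral spring.

#' Parameters of a synthetic island scene
#'
#' Defaults describe a Marion-like island: a ~1200 m peak, a day-time
#' sea-level mean near 7 degC, a 4 degC seasonal half-amplitude peaking in
#' January (austral summer), the standard environmental lapse rate of
#' -0.0065 degC/m, a 1 degC cooler windward (western) coast, nights 7 degC
#' colder than days, and modest slice/pixel noise. Scenes default to 5
#' years (60 monthly layers) so that full validation suites stay cheap;
#' the published records span 15 years (180 layers).
#'
#' @param shape Integer `c(n_rows, n_cols)`, at least 8 x 8.
#' @param peak_height Peak elevation in metres.
#' @param sea_level_temp Day-time sea-level annual mean, degC.
#' @param seasonal_amplitude Half-amplitude of the seasonal cycle, degC.
#' @param seasonal_phase Month (1-12) at which the cycle peaks.
#' @param lapse_rate Temperature change per metre of elevation, degC/m
#'   (must be <= 0).
#' @param windward_offset Temperature offset applied at the full-windward
#'   (western) edge, degC; tapers linearly to 0 at the eastern edge.
#' @param day_night_offset Day minus night temperature, degC.
#' @param slice_anomaly_sd SD of the shared per-layer anomaly, degC.
#' @param pixel_noise_sd SD of independent per-cell-per-layer noise, degC.
#' @param n_years Number of whole years simulated.
#' @param start_year First calendar year of the record.
#' @param seed Integer seed controlling all randomness of the scene.
#' @return A list of class `scene_params`.
#' @export
scene_params <- function(shape = c(40L, 40L), peak_height = 1200,
                         sea_level_temp = 7, seasonal_amplitude = 4,
                         seasonal_phase = 1L, lapse_rate = -0.0065,
                         windward_offset = -1, day_night_offset = 7,
                         slice_anomaly_sd = 1, pixel_noise_sd = 0.8,
                         n_years = 5L, start_year = 2001L, seed = 1L) {
  stopifnot(length(shape) == 2, all(shape >= 8),
            slice_anomaly_sd >= 0, pixel_noise_sd >= 0,
            n_years >= 1, lapse_rate <= 0,
            seasonal_phase >= 1, seasonal_phase <= 12)
  structure(
    list(shape = as.integer(shape), peak_height = peak_height,
         sea_level_temp = sea_level_temp,
         seasonal_amplitude = seasonal_amplitude,
         seasonal_phase = as.integer(seasonal_phase),
         lapse_rate = lapse_rate, windward_offset = windward_offset,
         day_night_offset = day_night_offset,
         slice_anomaly_sd = slice_anomaly_sd,
         pixel_noise_sd = pixel_noise_sd,
         n_years = as.integer(n_years), start_year = as.integer(start_year),
         seed = as.integer(seed)),
    class = "scene_params")
}

#' Parameters of the synthetic cloud-gap process
#'
#' Missingness follows a Bernoulli logit model
#' `logit P(missing) = b0 + b_elev * elev + b_day * [Day] + b_spring *
#' [Sep-Nov] + S_t(cell)` with `S_t` a smooth zero-mean spatial field
#' redrawn for every layer. Defaults produce roughly 10% missingness on the
#' default scene, matching the ~9.85% average gap fraction of the real
#' island records, with more gaps at altitude, by day, and in spring.
#'
#' @param intercept Baseline log-odds of a missing observation.
#' @param b_elev Log-odds change per metre of elevation.
#' @param b_day Log-odds offset for daytime layers.
#' @param b_spring Log-odds offset for austral spring (September-November).
#' @param spatial_field_sd SD of the smooth spatial logit field (0 turns
#'   spatial clustering off).
#' @param correlation_range Smoothing kernel scale of the field, in cells.
#' @param seed Integer seed.
#' @return A list of class `missingness_params`.
#' @export
missingness_params <- function(intercept = -3.9, b_elev = 0.002,
                               b_day = 0.5, b_spring = 0.5,
                               spatial_field_sd = 1, correlation_range = 3,
                               seed = 1L) {
  stopifnot(correlation_range > 0, spatial_field_sd >= 0)
  structure(
    list(intercept = intercept, b_elev = b_elev, b_day = b_day,
         b_spring = b_spring, spatial_field_sd = spatial_field_sd,
         correlation_range = correlation_range, seed = as.integer(seed)),
    class = "missingness_params")
}

# Evaluate an expression with a temporary RNG state seeded by `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Smooth zero-mean unit-SD random field: white noise convolved with a
# separable Gaussian kernel of scale `range` cells.
smooth_field <- function(n_rows, n_cols, range) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  half <- max(1L, ceiling(3 * range))
  k <- stats::dnorm(seq(-half, half), sd = range)
  k <- k / sum(k)
  Kr <- band_kernel(n_rows, k, half)
  Kc <- band_kernel(n_cols, k, half)
  f <- Kr %*% z %*% t(Kc)
  f <- f - mean(f)
  s <- stats::sd(as.vector(f))
  if (s > 0) f / s else f
}

# Row-normalized banded smoothing matrix (edges renormalized).
band_kernel <- function(n, k, half) {
  M <- matrix(0, n, n)
  for (d in -half:half) {
    i <- seq_len(n)
    j <- i + d
    ok <- j >= 1 & j <= n
    M[cbind(i[ok], j[ok])] <- k[d + half + 1]
  }
  M / rowSums(M)
}

#' Generate a synthetic island DEM
#'
#' A single smooth peak (Gaussian dome) centred on the grid, rescaled so
#' that the coast (elevation 0) falls at a fixed radius, plus low-amplitude
#' smooth roughness (2% of the peak height). Cells with elevation > 0 form
#' the land mask; off-island elevations are negative.
#'
#' @param params A [scene_params()].
#' @return A list with `dem` (a [dem_grid()]) and `land_mask`.
#' @export
make_dem <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  nr <- params$shape[1]; nc <- params$shape[2]
  if (nr < 8 || nc < 8) stop("scene shape must be at least 8 x 8")
  grid <- grid_meta(nr, nc, origin_lon = 37.5, origin_lat = -46.75)
  with_seed(params$seed, {
    rows <- (seq_len(nr) - (nr + 1) / 2) / (nr / 2)
    cols <- (seq_len(nc) - (nc + 1) / 2) / (nc / 2)
    r2 <- outer(rows^2, cols^2, "+")      # squared normalized radius
    dome <- exp(-r2 / (2 * 0.4^2))
    shore <- exp(-0.65^2 / (2 * 0.4^2))   # coast at normalized radius 0.65
    elev <- params$peak_height * (dome - shore) / (1 - shore)
    if (params$peak_height > 0) {
      rough <- smooth_field(nr, nc, 2) * 0.02 * params$peak_height
      elev <- elev + rough
    }
    land <- elev > 0
    if (!any(land)) stop("degenerate DEM: no land cells (peak_height too low)")
    if (mean(land) < 0.25) stop("degenerate DEM: fewer than 25% land cells")
    list(dem = dem_grid(grid, elev), land_mask = land)
  })
}

# Linear west->east windward ramp in [0, 1] (1 at the western edge).
windward_field <- function(n_rows, n_cols) {
  matrix(rep(seq(1, 0, length.out = n_cols), each = n_rows), n_rows, n_cols)
}

#' Simulate fully observed day and night LST cubes over a DEM
#'
#' For land cell c and layer t (month m): `T = T0 + A cos(2 pi (m - phase)
#' / 12) + lapse * elev(c) + W * windward(c) + eta_t + eps(c, t)` with
#' `eta_t ~ N(0, slice_anomaly_sd^2)` shared across the layer and
#' `eps` iid `N(0, pixel_noise_sd^2)`. The night cube repeats the
#' structure minus `day_night_offset`, with independent noise draws.
#'
#' @param dem A [dem_grid()].
#' @param params A [scene_params()].
#' @param land_mask Logical land mask matching the DEM.
#' @param name Island name recorded in the scene.
#' @return An [island_scene()] whose `day`/`night` cubes are fully observed
#'   over land; `truth` holds the same cubes for later error computation.
#' @export
simulate_lst <- function(dem, params, land_mask, name = "Synthia") {
  stopifnot(inherits(dem, "dem_grid"), inherits(params, "scene_params"))
  nr <- dem$grid$n_rows; nc <- dem$grid$n_cols
  stopifnot(all(dim(land_mask) == c(nr, nc)))
  labels <- ym_seq(params$start_year, params$n_years)
  nl <- length(labels)
  months <- ym_month(labels)
  ww <- windward_field(nr, nc)
  base <- params$lapse_rate * dem$elevation + params$windward_offset * ww
  season <- params$sea_level_temp +
    params$seasonal_amplitude * cos(2 * pi * (months - params$seasonal_phase) / 12)
  cube_for <- function(offset) {
    eta <- stats::rnorm(nl, 0, params$slice_anomaly_sd)
    vals <- array(NA_real_, c(nr, nc, nl))
    for (t in seq_len(nl)) {
      vals[, , t] <- season[t] - offset + base + eta[t] +
        matrix(stats::rnorm(nr * nc, 0, params$pixel_noise_sd), nr, nc)
    }
    vals
  }
  with_seed(params$seed + 1L, {
    day_vals <- cube_for(0)
    night_vals <- cube_for(params$day_night_offset)
    day <- lst_cube(dem$grid, day_vals, labels, "Day", land_mask)
    night <- lst_cube(dem$grid, night_vals, labels, "Night", land_mask)
    island_scene(name, dem, day, night,
                 truth = list(day = day, night = night),
                 provenance = list(params = unclass(params)))
  })
}

#' Simulate a cloud-gap missingness mask
#'
#' @param dem A [dem_grid()].
#' @param labels Integer YYYYMM labels of the layers to mask.
#' @param photoperiod `"Day"` or `"Night"`.
#' @param mparams A [missingness_params()].
#' @param spring_months Months counted as austral spring.
#' @return Logical array `n_rows x n_cols x n_layers`; `TRUE` marks cells
#'   to be set missing.
#' @export
simulate_cloud_mask <- function(dem, labels, photoperiod = c("Day", "Night"),
                                mparams = missingness_params(),
                                spring_months = 9:11) {
  photoperiod <- match.arg(photoperiod)
  stopifnot(inherits(dem, "dem_grid"), inherits(mparams, "missingness_params"))
  nr <- dem$grid$n_rows; nc <- dem$grid$n_cols
  labels <- check_ym_labels(labels)
  nl <- length(labels)
  months <- ym_month(labels)
  elev <- pmax(dem$elevation, 0)   # sea cells carry no elevation signal
  seed_off <- if (photoperiod == "Day") 0L else 10000L
  with_seed(mparams$seed + seed_off, {
    mask <- array(FALSE, c(nr, nc, nl))
    for (t in seq_len(nl)) {
      lp <- mparams$intercept + mparams$b_elev * elev +
        mparams$b_day * (photoperiod == "Day") +
        mparams$b_spring * (months[t] %in% spring_months)
      if (mparams$spatial_field_sd > 0) {
        lp <- lp + mparams$spatial_field_sd *
          smooth_field(nr, nc, mparams$correlation_range)
      }
      pr <- stats::plogis(lp)
      mask[, , t] <- matrix(stats::runif(nr * nc) < pr, nr, nc)
    }
    mask
  })
}

#' Apply a missingness mask to a cube
#'
#' @param cube An [lst_cube()].
#' @param mask Logical array congruent with the cube's values; `TRUE`
#'   entries are set to missing. A matrix is recycled over layers.
#' @return A new cube with masked cells missing; the input is unchanged.
#' @export
apply_mask <- function(cube, mask) {
  stopifnot(inherits(cube, "lst_cube"), is.logical(mask))
  if (length(dim(mask)) == 2L) {
    if (!all(dim(mask) == dim(cube$values)[1:2])) {
      stop("mask shape does not match cube")
    }
    mask <- array(mask, dim = dim(cube$values))
  }
  if (!all(dim(mask) == dim(cube$values))) {
    stop("mask shape does not match cube")
  }
  vals <- cube$values
  vals[mask] <- NA_real_
  cube_with_values(cube, vals)
}

#' Simulate a complete island scene
#'
#' Convenience wrapper: DEM, fully observed day/night truth cubes and,
#' when `mparams` is given, cloud-gap masks applied to both photoperiods.
#' Truth cubes are retained in `$truth`.
#'
#' @param params A [scene_params()].
#' @param mparams A [missingness_params()] or `NULL` for no gaps.
#' @param name Island name.
#' @return An [island_scene()].
#' @export
simulate_scene <- function(params = scene_params(), mparams = NULL,
                           name = "Synthia") {
  d <- make_dem(params)
  scene <- simulate_lst(d$dem, params, d$land_mask, name = name)
  if (!is.null(mparams)) {
    scene$day <- apply_mask(
      scene$day, simulate_cloud_mask(d$dem, scene$day$labels, "Day", mparams))
    scene$night <- apply_mask(
      scene$night, simulate_cloud_mask(d$dem, scene$night$labels, "Night",
                                       mparams))
    scene$provenance$missingness <- unclass(mparams)
  }
  scene
}

#' Simulate monthly soil-logger series from a scene
#'
#' Generates the ground-truth side of the microclimate comparison.
#' Shallow soil integrates surface forcing and damps the diurnal cycle,
#' so at each requested cell the monthly "soil" temperature is the AR(1)
#' smoothing of the day/night mean surface truth, plus a diurnal
#' deviation damped by `diurnal_damping` (soil by day is cooler than the
#' day surface, by night warmer than the night surface), plus logger
#' noise.
#'
#' @param scene An [island_scene()] with truth cubes.
#' @param cells Integer matrix with columns `row`, `col` of logger cells.
#' @param photoperiod `"Day"` or `"Night"`.
#' @param ar AR(1) smoothing coefficient in `[0, 1)`.
#' @param diurnal_damping Fraction of the diurnal half-range retained in
#'   soil (0 = fully buffered, 1 = tracks the surface).
#' @param noise_sd Logger noise SD, degC.
#' @param seed Integer seed.
#' @return A data.frame with `site`, `row`, `col`, `ym`, `soil_temp_c`.
#' @export
simulate_soil_monthly <- function(scene, cells, photoperiod = c("Day", "Night"),
                                  ar = 0.6, diurnal_damping = 0.3,
                                  noise_sd = 0.5, seed = 1L) {
  photoperiod <- match.arg(photoperiod)
  stopifnot(inherits(scene, "island_scene"), !is.null(scene$truth))
  sgn <- if (photoperiod == "Day") 1 else -1
  cells <- as.matrix(cells)
  with_seed(seed, {
    out <- lapply(seq_len(nrow(cells)), function(i) {
      d <- scene$truth$day$values[cells[i, 1], cells[i, 2], ]
      n <- scene$truth$night$values[cells[i, 1], cells[i, 2], ]
      surf <- (d + n) / 2 + sgn * diurnal_damping * (d - n) / 2
      soil <- stats::filter((1 - ar) * surf, ar, method = "recursive",
                            init = surf[1])
      data.frame(site = sprintf("site%02d", i),
                 row = unname(cells[i, 1]), col = unname(cells[i, 2]),
                 ym = scene$truth$day$labels,
                 soil_temp_c = as.numeric(soil) +
                   stats::rnorm(length(surf), 0, noise_sd))
    })
    do.call(rbind, out)
  })
}
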