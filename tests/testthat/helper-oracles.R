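# Independent oracles used across the suite. Each deliberately avoids the
# implementation path it checks.

# Brute-force pinball-loss minimizer: enumerate all basic solutions (fits
# through p points) and return the minimal loss and its coefficients.
rq_brute_force <- function(X, y, tau) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  best_loss <- Inf; best <- NULL
  for (idx in asplit(utils::combn(n, p), 2)) {
    XB <- X[idx, , drop = FALSE]
    if (abs(det(XB)) < 1e-12) next
    b <- solve(XB, y[idx])
    l <- sum((y - X %*% b) * (tau - ((y - X %*% b) < 0)))
    if (l < best_loss) { best_loss <- l; best <- b }
  }
  list(loss = best_loss, coefficients = best)
}

# Direct double-sum Moran's I with queen contiguity, row-standardized.
morans_brute <- function(mat) {
  keep <- which(!is.na(mat), arr.ind = TRUE)
  n <- nrow(keep)
  x <- mat[!is.na(mat)]
  z <- x - mean(x)
  # map (row, col) -> position in x (column-major order of non-NA cells)
  pos <- matrix(NA_integer_, nrow(mat), ncol(mat))
  pos[!is.na(mat)] <- seq_len(n)
  wmat <- matrix(0, n, n)
  for (i in seq_len(n)) {
    r <- keep[i, 1]; c <- keep[i, 2]
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nrow(mat) || cc < 1 || cc > ncol(mat)) next
      j <- pos[rr, cc]
      if (!is.na(j)) wmat[pos[r, c], j] <- 1
    }
  }
  rs <- rowSums(wmat)
  wmat[rs > 0, ] <- wmat[rs > 0, ] / rs[rs > 0]
  W <- sum(wmat)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- num + wmat[i, j] * z[i] * z[j]
  }
  (n / W) * num / sum(z^2)
}

# All-pairs Mann-Whitney U for the first sample.
mwu_brute <- function(x, y) {
  u <- 0
  for (xi in x) for (yi in y) {
    u <- u + (xi > yi) + 0.5 * (xi == yi)
  }
  u
}

# Independent bilinear interpolation of a DEM at an arbitrary lon/lat.
bilinear_oracle <- function(dem, lon, lat) {
  co <- grid_coords(dem$grid)
  ix <- max(1, min(findInterval(lon, co$lon), dem$grid$n_cols - 1))
  # lat descends; use reversed interval search
  iy <- max(1, min(findInterval(-lat, -co$lat), dem$grid$n_rows - 1))
  x1 <- co$lon[ix]; x2 <- co$lon[ix + 1]
  y1 <- co$lat[iy]; y2 <- co$lat[iy + 1]
  q11 <- dem$elevation[iy, ix]; q12 <- dem$elevation[iy, ix + 1]
  q21 <- dem$elevation[iy + 1, ix]; q22 <- dem$elevation[iy + 1, ix + 1]
  tx <- (lon - x1) / (x2 - x1); ty <- (lat - y1) / (y2 - y1)
  (1 - ty) * ((1 - tx) * q11 + tx * q12) + ty * ((1 - tx) * q21 + tx * q22)
}

# Independent sunrise/sunset (UTC hours): cooperative-extension style
# formulas (different declination/EoT approximations than the package).
sun_oracle <- function(date, lat, lon) {
  d <- as.integer(format(as.Date(date), "%j"))
  B <- 2 * pi * (d - 81) / 364
  eot <- 9.87 * sin(2 * B) - 7.53 * cos(B) - 1.5 * sin(B)   # minutes
  decl <- asin(sin(-23.44 * pi / 180) * cos(2 * pi / 365.24 * (d + 10) +
                 2 * 0.0167 * sin(2 * pi / 365.24 * (d - 2))))
  latr <- lat * pi / 180
  cos_ha <- (cos(90.833 * pi / 180) - sin(latr) * sin(decl)) /
    (cos(latr) * cos(decl))
  if (cos_ha > 1 || cos_ha < -1) return(c(NA, NA))
  ha <- acos(cos_ha) * 180 / pi
  solar_noon_utc <- 12 - lon / 15 - eot / 60
  c(sunrise = solar_noon_utc - ha / 15, sunset = solar_noon_utc + ha / 15)
}

# Small fully-observed cube on a linear-in-elevation field, constant in
# time: the exact-recovery workhorse.
linear_scene <- function(shape = c(16, 16), n_years = 2, seed = 7) {
  simulate_scene(scene_params(shape = shape, n_years = n_years,
                              seasonal_amplitude = 0, windward_offset = 0,
                              slice_anomaly_sd = 0, pixel_noise_sd = 0,
                              seed = seed))
}

default_test_scene <- function(shape = c(24, 24), n_years = 3, seed = 1,
                               mparams = missingness_params()) {
  simulate_scene(scene_params(shape = shape, n_years = n_years, seed = seed),
                 mparams)
}

# All-land scene: a deterministic lapse field over an elevation ramp with
# no sea cells, for window-geometry combinatorics.
full_land_scene <- function(shape = c(15, 15), n_years = 5) {
  g <- grid_meta(shape[1], shape[2])
  elev <- outer(seq(10, 800, length.out = shape[1]),
                seq(0, 150, length.out = shape[2]), "+")
  dem <- dem_grid(g, elev)
  labels <- ym_seq(2001, n_years)
  vals <- array(rep(12 - 0.006 * elev, length(labels)),
                c(shape[1], shape[2], length(labels)))
  list(dem = dem,
       cube = lst_cube(g, vals, labels, "Day",
                       matrix(TRUE, shape[1], shape[2])))
}

# Low-to-mid elevation logger cells spread over the island.
pick_sites <- function(scene, n = 6, elev_range = c(20, 350)) {
  ok <- which(scene$day$land_mask &
                scene$dem$elevation > elev_range[1] &
                scene$dem$elevation < elev_range[2], arr.ind = TRUE)
  sel <- ok[unique(round(seq(1, nrow(ok), length.out = n))), , drop = FALSE]
  cbind(row = sel[, 1], col = sel[, 2])
}
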