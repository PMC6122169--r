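# Ground-truthing against microclimate soil loggers: despiking, solar
# day/night labelling, monthly aggregation and the paired comparison of
# gap-filled vs un-filled surface products against soil temperatures.
#
# Logger data frames follow the schema
#   site, lat, lon, elevation_m, timestamp (POSIXct UTC), soil_temp_c

#' Remove spike artefacts from an hourly logger series
#'
#' Records whose absolute temperature change per hour from the last
#' retained record reaches `jump_threshold` are removed (the later record
#' of each offending pair), per site; a single spike therefore removes a
#' single record.
#'
#' @param series Data frame with at least `timestamp` and `soil_temp_c`;
#'   an optional `site` column groups independent series.
#' @param jump_threshold Spike threshold in degC per hour.
#' @return The series without spike records, plus an `n_removed`
#'   attribute.
#' @export
despike <- function(series, jump_threshold = 10) {
  stopifnot(all(c("timestamp", "soil_temp_c") %in% names(series)),
            jump_threshold > 0)
  grp <- if ("site" %in% names(series)) series$site else rep(1L, nrow(series))
  keep <- rep(TRUE, nrow(series))
  for (g in unique(grp)) {
    i <- which(grp == g)
    ts <- as.numeric(series$timestamp[i])
    if (is.unsorted(ts)) stop("timestamps must be increasing within a site")
    v <- series$soil_temp_c[i]
    last <- 1L
    for (k in seq_along(i)[-1]) {
      dt_h <- max((ts[k] - ts[last]) / 3600, 1e-9)
      if (abs(v[k] - v[last]) / dt_h >= jump_threshold) {
        keep[i[k]] <- FALSE
      } else {
        last <- k
      }
    }
  }
  out <- series[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Sunrise and sunset times (UTC)
#'
#' Standard solar-position equations (fractional-year Fourier expansions
#' for declination and the equation of time, hour-angle sunrise equation
#' with the refraction-adjusted zenith of 90.833 degrees).
#'
#' @param dates `Date` vector.
#' @param lat,lon Decimal degrees (longitude positive east).
#' @return Data frame with `sunrise` and `sunset` in UTC hours; polar day
#'   clamps to (0, 24) and polar night to (NA, NA).
#' @export
sunrise_sunset <- function(dates, lat, lon) {
  stopifnot(abs(lat) <= 90)
  dates <- as.Date(dates)
  doy <- as.integer(format(dates, "%j"))
  g <- 2 * pi / 365 * (doy - 1 + 0.5)        # fractional year at local noon
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                        0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  latr <- lat * pi / 180
  cos_ha <- cos(90.833 * pi / 180) / (cos(latr) * cos(decl)) -
    tan(latr) * tan(decl)
  ha <- acos(pmin(pmax(cos_ha, -1), 1)) * 180 / pi   # degrees
  sunrise <- (720 - 4 * (lon + ha) - eqtime) / 60
  sunset <- (720 - 4 * (lon - ha) - eqtime) / 60
  sunrise[cos_ha >= 1] <- NA_real_   # polar night: no sunrise
  sunset[cos_ha >= 1] <- NA_real_
  sunrise[cos_ha <= -1] <- 0         # polar day
  sunset[cos_ha <= -1] <- 24
  data.frame(sunrise = sunrise, sunset = sunset)
}

#' Label timestamps as Day or Night
#'
#' A record is `Day` iff its UTC time falls within `[sunrise, sunset)` of
#' its UTC date at the site. Polar night labels everything `Night`; polar
#' day everything `Day`.
#'
#' @param timestamps `POSIXct` vector (UTC).
#' @param lat,lon Site coordinates in decimal degrees.
#' @return Factor with levels `Day`, `Night`.
#' @export
day_night_split <- function(timestamps, lat, lon) {
  stopifnot(abs(lat) <= 90)
  timestamps <- as.POSIXct(timestamps, tz = "UTC")
  dates <- as.Date(timestamps, tz = "UTC")
  ss <- sunrise_sunset(dates, lat, lon)
  hours <- as.numeric(timestamps - as.POSIXct(dates, tz = "UTC"),
                      units = "hours")
  is_day <- !is.na(ss$sunrise) & hours >= ss$sunrise & hours < ss$sunset
  factor(ifelse(is_day, "Day", "Night"), levels = c("Day", "Night"))
}

#' Monthly day and night soil means per site
#'
#' @param series Despiked logger data frame (`site`, `timestamp`,
#'   `soil_temp_c`).
#' @param labels Factor of `Day`/`Night` labels from [day_night_split()].
#' @return Data frame `site, ym, photoperiod, soil_temp_c, n_records`,
#'   one row per site-month-photoperiod with any records.
#' @export
monthly_soil_means <- function(series, labels) {
  stopifnot(nrow(series) == length(labels))
  ym <- as.integer(format(as.Date(series$timestamp, tz = "UTC"), "%Y%m"))
  site <- if ("site" %in% names(series)) series$site else "site01"
  agg <- stats::aggregate(
    series$soil_temp_c,
    by = list(site = site, ym = ym, photoperiod = labels),
    FUN = function(v) c(mean = mean(v), n = length(v)))
  data.frame(site = agg$site, ym = agg$ym, photoperiod = agg$photoperiod,
             soil_temp_c = agg$x[, "mean"], n_records = agg$x[, "n"])
}

#' Mann-Whitney U test (normal approximation with tie correction)
#'
#' `U` counts pairs where a value of `x` exceeds a value of `y` (plus half
#' the ties), i.e. the U statistic of the first sample. The z score uses
#' the tie-corrected variance without continuity correction; the effect
#' size is `r = z / sqrt(n1 + n2)`.
#'
#' @param x,y Numeric samples.
#' @return List with `U`, `z`, `p`, `effect_r`, `n1`, `n2`.
#' @export
mwu_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 > 0, n2 > 0)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  N <- n1 + n2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  z <- if (sigma2 > 0) (U - n1 * n2 / 2) / sqrt(sigma2) else 0
  list(U = U, z = z, p = 2 * stats::pnorm(-abs(z)),
       effect_r = z / sqrt(N), n1 = n1, n2 = n2)
}

#' Compare a surface-temperature series to soil ground truth
#'
#' Aligns the two series on year-month, drops months whose soil mean is
#' below `exclude_below` (snow decouples soil from the surface in
#' sub-zero months), and reports the Pearson correlation, RMSE, and the
#' median and IQR of absolute errors. When a reference surface series is
#' supplied, a Mann-Whitney U test compares the two absolute-error
#' samples (U is the first series' statistic).
#'
#' @param lst Data frame `ym, value` of the surface product under test.
#' @param soil Data frame `ym, value` (or `soil_temp_c`) of soil means.
#' @param ref Optional second surface product for the U test.
#' @param exclude_below Exclusion threshold for soil means, degC.
#' @param min_pairs Minimum aligned pairs required.
#' @return A list of class `ground_comparison`: `pearson_r`, `rmse`,
#'   `median_abs_error`, `iqr_abs_error`, `n`, and (with `ref`) `mwu_U`,
#'   `mwu_z`, `mwu_p`, `effect_r`.
#' @export
compare_to_ground <- function(lst, soil, ref = NULL, exclude_below = 0,
                              min_pairs = 10) {
  soil_val <- if ("soil_temp_c" %in% names(soil)) soil$soil_temp_c else soil$value
  soil <- data.frame(ym = soil$ym, soil = soil_val)
  soil <- soil[!is.na(soil$soil) & soil$soil >= exclude_below, ]
  pairs_of <- function(prod) {
    m <- merge(data.frame(ym = prod$ym, value = prod$value), soil, by = "ym")
    m[!is.na(m$value), ]
  }
  m <- pairs_of(lst)
  if (nrow(m) < min_pairs) stop("insufficient aligned surface/soil pairs")
  abs_err <- abs(m$value - m$soil)
  out <- list(pearson_r = stats::cor(m$value, m$soil),
              rmse = sqrt(mean((m$value - m$soil)^2)),
              median_abs_error = stats::median(abs_err),
              iqr_abs_error = stats::IQR(abs_err),
              n = nrow(m))
  if (!is.null(ref)) {
    m2 <- pairs_of(ref)
    u <- mwu_test(abs_err, abs(m2$value - m2$soil))
    out$mwu_U <- u$U; out$mwu_z <- u$z; out$mwu_p <- u$p
    out$effect_r <- u$effect_r
  }
  structure(out, class = "ground_comparison")
}

#' @export
print.ground_comparison <- function(x, ...) {
  cat(sprintf("<ground_comparison> r=%.2f RMSE=%.2f median=%.2f IQR=%.2f n=%d",
              x$pearson_r, x$rmse, x$median_abs_error, x$iqr_abs_error, x$n))
  if (!is.null(x$mwu_U)) {
    cat(sprintf("  U=%.0f p=%.3g r=%.2f", x$mwu_U, x$mwu_p, x$effect_r))
  }
  cat("\n")
  invisible(x)
}

# Nearest-cell-centre mapping of site coordinates onto a grid.
site_cells <- function(sites, grid) {
  if (all(c("row", "col") %in% names(sites))) {
    return(cbind(row = sites$row, col = sites$col))
  }
  co <- grid_coords(grid)
  cbind(row = vapply(sites$lat, function(la) which.min(abs(co$lat - la)),
                     integer(1)),
        col = vapply(sites$lon, function(lo) which.min(abs(co$lon - lo)),
                     integer(1)))
}

#' The Marion-style ground-truthing protocol
#'
#' Randomly deletes a fraction of the observed surface values (for sample
#' balance between products), gap-fills, and compares the gap-filled
#' predictions (at knocked-out site-months) and the remaining un-filled
#' observations against monthly soil means at the logger cells, per
#' photoperiod.
#'
#' @param scene An [island_scene()].
#' @param soil_monthly List with elements `Day` and `Night`, each a data
#'   frame `site, ym, soil_temp_c` plus either `row`/`col` or `lat`/`lon`
#'   site coordinates.
#' @param knockout_fraction Fraction of observed values deleted before
#'   gap-filling (0 skips the knockout; both products are then the
#'   observations).
#' @param spec A [subset_spec()].
#' @param exclude_below Soil-mean exclusion threshold, degC.
#' @param seed Integer seed.
#' @return A list of class `ground_truth_report`, per photoperiod:
#'   `filled` and `unfilled` [compare_to_ground()] results (the `filled`
#'   one carries the U test against `unfilled`).
#' @export
ground_truth_protocol <- function(scene, soil_monthly, knockout_fraction = 0.5,
                                  spec = subset_spec(), exclude_below = 0,
                                  seed = 1L) {
  stopifnot(inherits(scene, "island_scene"))
  out <- list()
  for (pp in c("Day", "Night")) {
    cube <- if (pp == "Day") scene$day else scene$night
    soil <- soil_monthly[[pp]]
    stopifnot(all(c("site", "ym", "soil_temp_c") %in% names(soil)))
    sites <- unique(soil[, setdiff(names(soil), c("ym", "soil_temp_c")),
                         drop = FALSE])
    cells <- site_cells(sites, cube$grid)
    if (knockout_fraction > 0) {
      ko <- knockout_random(cube, knockout_fraction,
                            seed = seed + (pp == "Night"))
      res <- gapfill_cube(ko$cube, scene$dem, spec, max_missing_pct = 100)
      deleted <- array(FALSE, dim(cube$values))
      deleted[ko$deleted] <- TRUE
    } else {
      res <- NULL
      deleted <- array(FALSE, dim(cube$values))
    }
    filled_rows <- list(); unfilled_rows <- list()
    for (i in seq_len(nrow(sites))) {
      r <- cells[i, 1]; cl <- cells[i, 2]
      obs_series <- cube$values[r, cl, ]
      if (knockout_fraction > 0) {
        fill_series <- res$mean$values[r, cl, ]
        was_del <- deleted[r, cl, ]
        filled_vals <- ifelse(was_del, fill_series, NA_real_)
        unfilled_vals <- ifelse(was_del, NA_real_, obs_series)
      } else {
        filled_vals <- obs_series
        unfilled_vals <- obs_series
      }
      site_id <- sites$site[i]
      filled_rows[[i]] <- data.frame(site = site_id, ym = cube$labels,
                                     value = filled_vals)
      unfilled_rows[[i]] <- data.frame(site = site_id, ym = cube$labels,
                                       value = unfilled_vals)
    }
    # pool sites by aligning on (site, ym): fold site into the key
    fold <- function(df) data.frame(ym = paste(df$site, df$ym),
                                    value = df$value)
    soil_k <- data.frame(ym = paste(soil$site, soil$ym),
                         soil_temp_c = soil$soil_temp_c)
    filled <- fold(do.call(rbind, filled_rows))
    unfilled <- fold(do.call(rbind, unfilled_rows))
    out[[pp]] <- list(
      filled = compare_to_ground(filled, soil_k, ref = unfilled,
                                 exclude_below = exclude_below),
      unfilled = compare_to_ground(unfilled, soil_k,
                                   exclude_below = exclude_below))
  }
  structure(c(out, list(knockout_fraction = knockout_fraction,
                        seed = as.integer(seed))),
            class = "ground_truth_report")
}
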