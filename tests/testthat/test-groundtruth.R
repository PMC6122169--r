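hourly_series <- function(n_hours = 24 * 40, start = "2005-01-01",
                          fun = function(h) 5 + 3 * sin(2 * pi * h / 24)) {
  ts <- as.POSIXct(start, tz = "UTC") + 3600 * (seq_len(n_hours) - 1)
  data.frame(site = "s1", timestamp = ts,
             soil_temp_c = fun(seq_len(n_hours)))
}

test_that("despike removes only above-threshold hourly jumps", {
  smooth <- hourly_series()
  expect_identical(despike(smooth)$soil_temp_c, smooth$soil_temp_c)
  expect_equal(attr(despike(smooth), "n_removed"), 0)

  spiked <- smooth
  spiked$soil_temp_c[100] <- spiked$soil_temp_c[99] + 12
  out <- despike(spiked)
  expect_equal(attr(out, "n_removed"), 1)
  expect_false(spiked$soil_temp_c[100] %in% out$soil_temp_c)

  expect_identical(nrow(despike(spiked, jump_threshold = Inf)),
                   nrow(spiked))
})

test_that("day/night split matches solar geometry", {
  # equator, equinox: about 12 h of daylight
  ss <- sunrise_sunset(as.Date("2010-03-20"), 0, 0)
  expect_lt(abs((ss$sunset - ss$sunrise) - 12), 0.2)
  # polar night at 80N in December
  ss2 <- sunrise_sunset(as.Date("2010-12-21"), 80, 0)
  expect_true(is.na(ss2$sunrise))
  labs <- day_night_split(as.POSIXct("2010-12-21 12:00", tz = "UTC"), 80, 0)
  expect_identical(as.character(labs), "Night")
  # polar day at 80N in June
  labs2 <- day_night_split(as.POSIXct("2010-06-21 00:30", tz = "UTC"), 80, 0)
  expect_identical(as.character(labs2), "Day")
  expect_error(day_night_split(Sys.time(), 95, 0))

  # Marion Island solstices within 10 minutes of an independent oracle
  for (d in c("2008-12-21", "2008-06-21")) {
    got <- sunrise_sunset(as.Date(d), -46.908, 37.7424)
    want <- sun_oracle(d, -46.908, 37.7424)
    expect_lt(abs(got$sunrise - want["sunrise"]), 10 / 60)
    expect_lt(abs(got$sunset - want["sunset"]), 10 / 60)
  }
})

test_that("daylength varies continuously and complements night length", {
  d <- as.Date("2011-04-01")
  lens <- vapply(seq(-60, 60, 5), function(lat) {
    ss <- sunrise_sunset(d, lat, 20)
    ss$sunset - ss$sunrise
  }, numeric(1))
  expect_true(all(abs(diff(lens)) < 1.5))   # no jumps away from the poles
  expect_true(all(lens > 0 & lens < 24))
  # day + night = 24 h by construction of a single sunrise/sunset pair
  ss <- sunrise_sunset(d, -46.9, 37.7)
  expect_equal((ss$sunset - ss$sunrise) + (24 - ss$sunset + ss$sunrise), 24)
})

test_that("monthly soil means equal the group-by oracle", {
  set.seed(6)
  s <- hourly_series(24 * 90, fun = function(h) rnorm(length(h), 4, 2))
  labels <- day_night_split(s$timestamp, -46.9, 37.74)
  out <- monthly_soil_means(s, labels)
  ym <- as.integer(format(as.Date(s$timestamp, tz = "UTC"), "%Y%m"))
  for (i in sample(nrow(out), 4)) {
    sel <- ym == out$ym[i] & labels == out$photoperiod[i]
    expect_equal(out$soil_temp_c[i], mean(s$soil_temp_c[sel]))
    expect_equal(out$n_records[i], sum(sel))
  }
  # a month with no records is absent, not zero
  gap <- s[format(s$timestamp, "%m") != "02", ]
  out2 <- monthly_soil_means(gap, day_night_split(gap$timestamp, -46.9, 37.74))
  expect_false(200502L %in% out2$ym)
  # constant series: every mean is the constant
  cs <- hourly_series(24 * 60, fun = function(h) rep(5, length(h)))
  outc <- monthly_soil_means(cs, day_night_split(cs$timestamp, -46.9, 37.74))
  expect_true(all(outc$soil_temp_c == 5))
})

test_that("Mann-Whitney U matches all-pairs enumeration", {
  expect_equal(mwu_test(c(1, 2, 3), c(4, 5, 6))$U, 0)
  expect_equal(mwu_test(c(4, 5, 6), c(1, 2, 3))$U, 9)
  set.seed(19)
  for (rep in 1:20) {
    x <- sample(1:8, sample(3:10, 1), replace = TRUE)
    y <- sample(1:8, sample(3:10, 1), replace = TRUE)
    got <- mwu_test(x, y)
    expect_equal(got$U, mwu_brute(x, y))
    # exchange symmetry: U <-> n1 n2 - U, z <-> -z
    swapped <- mwu_test(y, x)
    expect_equal(swapped$U, length(x) * length(y) - got$U)
    expect_equal(swapped$z, -got$z, tolerance = 1e-12)
    expect_equal(swapped$p, got$p, tolerance = 1e-12)
  }
  # agreement with the reference implementation (no continuity correction)
  set.seed(23)
  x <- rnorm(40); y <- rnorm(35, 0.5)
  ref <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
  got <- mwu_test(x, y)
  expect_equal(got$U, unname(ref$statistic))
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
})

test_that("compare_to_ground reports exact identities", {
  months <- ym_seq(2005, 2)
  set.seed(9)
  soil <- data.frame(ym = months, value = runif(24, 1, 10))
  same <- data.frame(ym = months, value = soil$value)
  cg <- compare_to_ground(same, soil)
  expect_equal(cg$pearson_r, 1)
  expect_equal(cg$rmse, 0)
  expect_equal(cg$median_abs_error, 0)
  shifted <- data.frame(ym = months, value = soil$value + 2)
  cg2 <- compare_to_ground(shifted, soil)
  expect_equal(cg2$pearson_r, 1)
  expect_equal(cg2$rmse, 2)
  expect_equal(cg2$median_abs_error, 2)
  expect_equal(cg2$iqr_abs_error, 0)
  # sub-zero soil months are excluded
  soil3 <- soil; soil3$value[1:16] <- -5
  expect_error(compare_to_ground(same, soil3), "insufficient")
  cg3 <- compare_to_ground(same, transform(soil, value = value - 1),
                           exclude_below = -Inf)
  expect_equal(cg3$n, 24)
})

test_that("the ground-truth protocol behaves at its limits", {
  sc <- default_test_scene(shape = c(20, 20), n_years = 3, seed = 4)
  cells <- pick_sites(sc, n = 6)   # low/mid-elevation loggers
  soil <- lapply(c(Day = "Day", Night = "Night"), function(pp) {
    s <- simulate_soil_monthly(sc, cells, pp, seed = 5)
    s[, c("site", "row", "col", "ym", "soil_temp_c")]
  })
  # knockout_fraction = 0: both products identical, identical comparisons
  gt0 <- ground_truth_protocol(sc, soil, knockout_fraction = 0, seed = 2)
  for (pp in c("Day", "Night")) {
    f <- gt0[[pp]]$filled; u <- gt0[[pp]]$unfilled
    expect_equal(f$pearson_r, u$pearson_r)
    expect_equal(f$rmse, u$rmse)
    expect_equal(f$n, u$n)
  }
  # full protocol: comparable correlations between products, reproducible
  gt <- ground_truth_protocol(sc, soil, knockout_fraction = 0.5, seed = 2)
  gt_again <- ground_truth_protocol(sc, soil, knockout_fraction = 0.5, seed = 2)
  expect_identical(gt$Day$filled$pearson_r, gt_again$Day$filled$pearson_r)
  expect_identical(gt$Night$filled$mwu_U, gt_again$Night$filled$mwu_U)
  for (pp in c("Day", "Night")) {
    expect_lt(abs(gt[[pp]]$filled$pearson_r - gt[[pp]]$unfilled$pearson_r), 0.25)
    expect_true(abs(gt[[pp]]$filled$effect_r) <= 1)
  }
})
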