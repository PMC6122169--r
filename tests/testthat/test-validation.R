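test_that("random knockout deletes exactly round(f * n) observed cells", {
  sc <- default_test_scene(shape = c(16, 16), n_years = 2, mparams = NULL)
  cube <- sc$day
  n_obs <- sum(!is.na(cube$values))
  ko <- knockout_random(cube, 0.1, seed = 4)
  expect_equal(length(ko$deleted), round(0.1 * n_obs))
  # deleted set was observed, disjoint from the originally-missing set
  expect_true(all(!is.na(cube$values[ko$deleted])))
  expect_true(all(is.na(ko$cube$values[ko$deleted])))
  # determinism
  ko2 <- knockout_random(cube, 0.1, seed = 4)
  expect_identical(ko$deleted, ko2$deleted)
  expect_false(identical(ko$deleted, knockout_random(cube, 0.1, seed = 5)$deleted))
  expect_error(knockout_random(cube, 0), "fraction")
  expect_error(knockout_random(cube, 1))
})

test_that("clustered knockout deletes 3x3 blocks with bounded overshoot", {
  # single-layer fully observed 10x10 cube
  g <- grid_meta(10, 10)
  cube <- lst_cube(g, array(1, c(10, 10, 1)), 200101L)
  # a tiny target stops after one draw: a single (possibly truncated) block
  ko <- knockout_clustered(cube, 0.01, seed = 1)
  first_blocks <- sum(is.na(ko$cube$values))
  expect_true(first_blocks %in% c(9, 6, 4))  # interior, edge or corner block
  pos <- which(is.na(ko$cube$values[, , 1]), arr.ind = TRUE)
  expect_lte(diff(range(pos[, 1])), 2)
  expect_lte(diff(range(pos[, 2])), 2)

  # corner centre truncates to 4 deletions: force by tiny grid
  g3 <- grid_meta(2, 2)
  cube3 <- lst_cube(g3, array(1, c(2, 2, 1)), 200101L)
  ko3 <- knockout_clustered(cube3, 0.9, seed = 2)
  expect_equal(length(ko3$deleted), 4)       # one block covers the grid

  # overshoot bound: achieved in [f, f + 9/n]
  sc <- default_test_scene(shape = c(20, 20), n_years = 2, mparams = NULL)
  n_obs <- sum(!is.na(sc$day$values))
  kc <- knockout_clustered(sc$day, 0.10, seed = 6)
  expect_gte(kc$achieved_fraction, 0.10)
  expect_lte(kc$achieved_fraction, 0.10 + 9 / n_obs)
  expect_identical(knockout_clustered(sc$day, 0.10, seed = 6)$deleted,
                   kc$deleted)
})

test_that("error statistics match their closed forms and identities", {
  expect_equal(unclass(error_stats(c(1, 2, 3), c(1, 2, 3)))[1:4],
               list(rmse = 0, mean_error = 0, error_range = 0, error_sd = 0))
  st <- error_stats(c(0, 2), c(1, 1))     # errors +1, -1
  expect_equal(st$rmse, 1)
  expect_equal(st$mean_error, 0)
  expect_equal(st$error_range, 2)
  expect_equal(st$error_sd, sqrt(2), tolerance = 1e-12)

  set.seed(14)
  pred <- rnorm(500); tr <- rnorm(500)
  pred[sample(500, 12)] <- NA
  st2 <- error_stats(pred, tr)
  e <- (tr - pred)[!is.na(pred)]
  expect_equal(st2$rmse, sqrt(mean(e^2)))
  expect_equal(st2$mean_error, mean(e))
  expect_equal(st2$error_range, max(e) - min(e))
  expect_equal(st2$error_sd, sd(e))
  expect_equal(st2$n_failed, 12)
  # rmse^2 = mean^2 + sd^2 (n-1)/n
  expect_equal(st2$rmse^2,
               st2$mean_error^2 + st2$error_sd^2 * (st2$n - 1) / st2$n)
  expect_error(error_stats(rep(NA_real_, 5), rnorm(5)), "no successfully")
})

test_that("support-error regression: exact fits, null behaviour, brute force", {
  # exactly linear: V_full = 0, pseudo-r2 = 1
  s <- rep(100:119, 3)
  fit <- support_error_qr(0.5 + 0.002 * s, s, n_boot = 50, seed = 2)
  expect_equal(fit$pseudo_r2, 1)
  expect_equal(fit$slope, 0.002, tolerance = 1e-9)
  expect_equal(fit$mean_support, mean(s))
  expect_equal(fit$min_support, 100)

  # null: errors independent of support; p > 0.05 in >= 90% of replicates
  set.seed(77)
  rejections <- vapply(1:20, function(b) {
    e <- abs(rnorm(2000))
    sup <- sample(100:1800, 2000, replace = TRUE)
    support_error_qr(e, sup, n_boot = 100, seed = b)$p <= 0.05
  }, logical(1))
  expect_gte(mean(!rejections), 0.9)

  # small datasets match brute-force enumeration over two-point lines
  set.seed(3)
  for (rep in 1:5) {
    e <- abs(rnorm(12)); sup <- sample(1:40, 12)
    fit <- support_error_qr(e, sup, n_boot = 20, seed = rep)
    oracle <- rq_brute_force(cbind(1, sup), e, 0.5)
    got <- pinball_loss(e - cbind(1, sup) %*% c(fit$intercept, fit$slope), 0.5)
    expect_lt(got - oracle$loss, 1e-8)
  }
  expect_error(support_error_qr(abs(rnorm(20)), rep(5, 20)), "constant")
  expect_error(support_error_qr(1:5, 1:5), "at least 10")
})

test_that("Moran's I equals the brute-force double sum", {
  # expected value is -1/(n-1)
  set.seed(21)
  m <- matrix(rnorm(100), 10, 10)
  mt <- morans_i(m)
  expect_equal(mt$expected_I, -1 / 99)

  # checkerboard: strong negative autocorrelation, matches brute force
  cb <- matrix((outer(1:5, 1:5, "+") %% 2), 5, 5)
  mt_cb <- morans_i(cb)
  expect_lt(mt_cb$I, mt_cb$expected_I)
  expect_lt(abs(mt_cb$I - morans_brute(cb)), 1e-12)

  # random field with NAs vs brute force
  m2 <- matrix(rnorm(64), 8, 8)
  m2[sample(64, 10)] <- NA
  expect_lt(abs(morans_i(m2)$I - morans_brute(m2)), 1e-12)

  # smooth gradient: significant positive autocorrelation
  gr <- outer(1:9, 1:9, "+") + matrix(rnorm(81, 0, 0.1), 9, 9)
  mtg <- morans_i(gr)
  expect_gt(mtg$I, 0)
  expect_lt(mtg$p, 0.05)

  expect_error(morans_i(matrix(1, 6, 6)), "constant")
  expect_error(morans_i(matrix(rnorm(4), 2, 2)), "at least 9")
})

test_that("missingness GLM recovers simulated coefficients", {
  set.seed(31)
  n <- 50000
  elev <- runif(n, 0, 1500)
  pp <- sample(c("Day", "Night"), n, replace = TRUE)
  season <- sample(c("spring", "other"), n, replace = TRUE)
  lp <- -2 + 0.002 * elev + 0.4 * (pp == "Day") + 0.3 * (season == "spring")
  y <- rbinom(n, 1, plogis(lp))
  tab <- data.frame(is_missing = y, photoperiod = pp, season = season,
                    elevation = elev)
  fit <- missingness_glm(tab)
  co <- fit$coefficients
  b_elev <- co[co$term == "elevation", ]
  expect_lt(abs(b_elev$estimate - 0.002), 3 * b_elev$se)
  expect_false(fit$separation)
  expect_error(missingness_glm(transform(tab, is_missing = 0)), "classes")
})

test_that("missingness GLM type-I error is calibrated under b_elev = 0", {
  set.seed(55)
  inside <- vapply(1:40, function(b) {
    n <- 4000
    elev <- runif(n, 0, 1500)
    tab <- data.frame(is_missing = rbinom(n, 1, 0.2),
                      photoperiod = sample(c("Day", "Night"), n, TRUE),
                      season = sample(c("spring", "other"), n, TRUE),
                      elevation = elev)
    co <- missingness_glm(tab)$coefficients
    abs(co[co$term == "elevation", "z"]) < 1.96
  }, logical(1))
  expect_gte(mean(inside), 0.85)   # ~95% nominal coverage
})

test_that("negative-binomial GLM recovers simulated coefficients", {
  set.seed(41)
  n <- 20000
  elev <- runif(n, 0, 1500)
  pp <- sample(c("Day", "Night"), n, replace = TRUE)
  mu <- exp(0.5 + 0.001 * elev + 0.3 * (pp == "Day"))
  cnt <- rnbinom(n, size = 2, mu = mu)
  fit <- error_freq_glm(data.frame(count = cnt, photoperiod = pp,
                                   elevation = elev))
  b <- fit$coefficients[fit$coefficients$term == "elevation", ]
  expect_lt(abs(b$estimate - 0.001), 3 * b$se)
  expect_gt(fit$theta, 1)
  expect_lt(fit$theta, 4)

  # zero-effect: CI covers 0 in most replicates
  covered <- vapply(1:20, function(b) {
    cnt0 <- rnbinom(3000, size = 2, mu = 3)
    f <- error_freq_glm(data.frame(count = cnt0,
                                   photoperiod = sample(c("Day", "Night"),
                                                        3000, TRUE),
                                   elevation = runif(3000, 0, 1500)))
    co <- f$coefficients[f$coefficients$term == "elevation", ]
    abs(co$estimate) < 1.96 * co$se
  }, logical(1))
  expect_gte(mean(covered), 0.85)
  expect_error(error_freq_glm(data.frame(count = rep(0, 50),
                                         photoperiod = "Day",
                                         elevation = runif(50))),
               "zero")
})

test_that("run_validation_suite produces Table-2/3-shaped reports", {
  sc <- default_test_scene(shape = c(16, 16), n_years = 2,
                           mparams = missingness_params(intercept = -4.5))
  rep1 <- suppressWarnings(
    run_validation_suite(sc, "random", fractions = 0.1, seed = 3))
  expect_equal(nrow(rep1$errors), 2)           # one row per photoperiod
  expect_null(rep1$support_fits)
  expect_true(all(c("rmse", "mean_error", "error_range", "error_sd",
                    "n_failed") %in% names(rep1$errors)))

  repc <- suppressWarnings(
    run_validation_suite(sc, "clustered", fractions = 0.1, seed = 3,
                         photoperiods = "Day"))
  expect_equal(nrow(repc$support_fits), 1)
  expect_true(all(c("mean_support", "min_support", "slope", "slope_se",
                    "pseudo_r2", "t", "p") %in% names(repc$support_fits)))
  expect_true(repc$support_fits$pseudo_r2 >= 0 &&
                repc$support_fits$pseudo_r2 <= 1)
  # determinism of the whole suite
  rep2 <- suppressWarnings(
    run_validation_suite(sc, "random", fractions = 0.1, seed = 3))
  expect_identical(rep1$errors, rep2$errors)
})

test_that("noise-free scenes validate with essentially zero error", {
  sc <- linear_scene(shape = c(14, 14), n_years = 2)
  rep <- run_validation_suite(sc, "random", fractions = c(0.05, 0.3),
                              seed = 2, photoperiods = "Day")
  expect_true(all(rep$errors$rmse < 1e-6))
  expect_true(all(rep$errors$n_failed == 0))
})
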