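test_that("clip range equals the observed extremes", {
  g <- grid_meta(3, 3)
  cube <- lst_cube(g, array(4, c(3, 3, 2)), c(200101L, 200102L))
  expect_equal(compute_clip_range(cube), c(4, 4))
  vals <- array(NA_real_, c(3, 3, 2))
  vals[1, 1, 1] <- -3; vals[2, 2, 1] <- 0; vals[3, 3, 2] <- 21.5
  cube2 <- lst_cube(g, vals, c(200101L, 200102L))
  expect_equal(compute_clip_range(cube2), c(-3, 21.5))
  set.seed(9)
  vals3 <- array(rnorm(18), c(3, 3, 2))
  cube3 <- lst_cube(g, vals3, c(200101L, 200102L))
  expect_equal(compute_clip_range(cube3), range(vals3))
  empty <- lst_cube(g, array(NA_real_, c(3, 3, 2)), c(200101L, 200102L))
  expect_error(compute_clip_range(empty), "all-missing")
})

test_that("clip_mean clamps point predictions only", {
  expect_equal(clip_mean(30, c(-10, 25)), 25)
  expect_equal(clip_mean(12, c(-10, 25)), 12)
  expect_equal(clip_mean(-40, c(-10, 25)), -10)
})

test_that("subset geometry matches the search strategy combinatorics", {
  sc <- linear_scene(shape = c(15, 15), n_years = 5)
  cube <- sc$day
  dem <- sc$dem
  spec <- subset_spec()
  # interior cell, mid-series: 11x11 cells x (3 months x 5 years) slices
  mid_layer <- match(200306L, cube$labels)
  sub <- extract_subset(cube, dem, c(8, 8), mid_layer, spec)
  expect_equal(nrow(sub$values), 121)
  expect_equal(ncol(sub$values), 15)
  # corner cell: 6x6 truncated window
  sub_corner <- extract_subset(cube, dem, c(1, 1), mid_layer, spec)
  expect_equal(nrow(sub_corner$values), 36)
  # first year: only year offsets >= 0 remain (3 months x 3 years)
  sub_edge <- extract_subset(cube, dem, c(8, 8), match(200106L, cube$labels),
                             spec)
  expect_equal(ncol(sub_edge$values), 9)
  expect_true(all(ym_year(sub_edge$slice_labels) >= 2001))
  # month offsets cross year boundaries
  sub_jan <- extract_subset(cube, dem, c(8, 8), match(200301L, cube$labels),
                            spec)
  expect_true(200212L %in% sub_jan$slice_labels)
  expect_error(extract_subset(cube, dem, c(8, 8), 999901L), "absent")
})

test_that("support counts observed entries excluding the target", {
  fl <- full_land_scene(c(15, 15), n_years = 5)
  mid_layer <- match(200306L, fl$cube$labels)
  sub <- extract_subset(fl$cube, fl$dem, c(8, 8), mid_layer)
  expect_equal(count_support(sub), 121 * 15 - 1)        # 1814
  # fully missing subset
  empty <- sub
  empty$values[] <- NA_real_
  expect_equal(count_support(empty), 0)
  # hand-built 3-cell x 2-slice subset with 4 observations
  hand <- structure(
    list(values = matrix(c(1, NA, 2, 3, NA, 4), 3, 2),
         elev = c(0, 100, 200), slice_labels = c(200101L, 200102L),
         target_cell = 2L, target_slice = 1L),
    class = "st_subset")
  expect_equal(count_support(hand), 4)
})

test_that("tau* follows the normalized mid-rank of the target cell", {
  # target is the maximum in every slice of >= 5 observed cells
  mk <- function(vals, target_cell, target_slice = 1L) {
    structure(list(values = vals, elev = seq_len(nrow(vals)) * 10,
                   slice_labels = ym_seq(2001, 1)[seq_len(ncol(vals))],
                   target_cell = target_cell, target_slice = target_slice),
              class = "st_subset")
  }
  set.seed(2)
  v <- matrix(runif(5 * 4), 5, 4)
  v[5, ] <- 2                          # target cell is always the max
  sub <- mk(v, 5L, 2L)
  sub$values[5, 2] <- NA               # the entry being predicted
  expect_gte(estimate_target_quantile(sub), 0.8)
  # target observed nowhere: fallback 0.5
  v2 <- matrix(runif(12), 4, 3)
  v2[2, ] <- NA
  expect_equal(estimate_target_quantile(mk(v2, 2L)), 0.5)
  # single other cell per slice, target always below it
  v3 <- rbind(c(0, 0, 0), c(5, 5, 5))
  sub3 <- mk(v3, 1L, 2L)
  sub3$values[1, 2] <- NA
  expect_lt(estimate_target_quantile(sub3), 0.5)
})

test_that("qr_predict handles constant data, exact fields and failure", {
  sc <- linear_scene(shape = c(15, 15), n_years = 5)
  mid_layer <- match(200306L, sc$day$labels)
  # constant data
  cube_const <- cube_c <- sc$day
  cube_c$values[!is.na(cube_c$values)] <- 3.25
  sub <- extract_subset(cube_c, sc$dem, c(8, 8), mid_layer)
  pr <- qr_predict(sub, 0.5)
  expect_false(pr$failed)
  expect_equal(c(pr$lower, pr$mean, pr$upper), rep(3.25, 3), tolerance = 1e-9)

  # noise-free lapse field: exact linear recovery at the target elevation
  sub2 <- extract_subset(sc$day, sc$dem, c(8, 8), mid_layer)
  pr2 <- qr_predict(sub2, 0.5)
  p <- scene_params()
  expt <- p$sea_level_temp + p$lapse_rate * sc$dem$elevation[8, 8]
  expect_lt(abs(pr2$mean - expt), 1e-6)

  # support below n_min is a failure signal, not an exception
  sub3 <- sub2
  sub3$values[] <- NA_real_
  pr3 <- qr_predict(sub3, 0.5, subset_spec())
  expect_true(pr3$failed)
  expect_equal(pr3$support, 0)
})

test_that("gapfill_cube honours its output contract", {
  sc <- default_test_scene(shape = c(18, 18), n_years = 2, seed = 5)
  cube <- sc$day
  dem <- sc$dem
  res <- gapfill_cube(cube, dem)
  obs_idx <- which(!is.na(cube$values))
  # pass-through of observations
  expect_identical(res$mean$values[obs_idx], cube$values[obs_idx])
  expect_true(all(is.na(res$lower_ci$values[obs_idx])))
  expect_true(all(is.na(res$upper_ci$values[obs_idx])))
  # filled cells: CI order and clipping
  fill_idx <- which(is.na(cube$values) & !is.na(res$mean$values))
  expect_gt(length(fill_idx), 0)
  expect_true(all(res$lower_ci$values[fill_idx] <=
                    res$mean$values[fill_idx] + 1e-9))
  expect_true(all(res$mean$values[fill_idx] <=
                    res$upper_ci$values[fill_idx] + 1e-9))
  expect_true(all(res$mean$values[fill_idx] >= res$clip_range[1] - 1e-12))
  expect_true(all(res$mean$values[fill_idx] <= res$clip_range[2] + 1e-12))
  # the obs cube is the input
  expect_identical(res$obs$values, cube$values)
  # determinism
  res2 <- gapfill_cube(cube, dem)
  expect_identical(res2$mean$values, res$mean$values)
})

test_that("a fully observed cube gap-fills to itself", {
  sc <- linear_scene(shape = c(12, 12), n_years = 1)
  res <- gapfill_cube(sc$day, sc$dem)
  expect_identical(res$mean$values, sc$day$values)
  expect_equal(res$n_filled + res$n_failed, 0)
  expect_true(all(is.na(res$lower_ci$values)))
})

test_that("months missing across all cells and neighbours fail (McDonald mode)", {
  sc <- linear_scene(shape = c(12, 12), n_years = 1)
  cube <- sc$day
  kill <- match(c(200105L, 200106L, 200107L), cube$labels)
  cube$values[, , kill] <- NA_real_
  res <- gapfill_cube(cube, sc$dem)
  land <- sum(cube$land_mask)
  mid <- match(200106L, cube$labels)
  expect_true(all(res$failed[, , mid][cube$land_mask]))
  expect_true(all(is.na(res$mean$values[, , mid])))
  # flanking months borrow from their outer neighbours and succeed
  expect_false(any(res$failed[, , match(200105L, cube$labels)][cube$land_mask]))
  expect_equal(res$n_failed, land)
})

test_that("10% random gaps on a default scene all fill with zero failures", {
  sc <- default_test_scene(shape = c(18, 18), n_years = 2, mparams = NULL)
  ko <- knockout_random(sc$day, 0.10, seed = 21)
  res <- gapfill_cube(ko$cube, sc$dem)
  expect_equal(res$n_failed, 0)
  expect_equal(res$n_filled, length(ko$deleted))
  expect_true(all(!is.na(res$mean$values[ko$deleted])))
})

test_that("gap-fill beats the climatological month-mean imputer", {
  sc <- default_test_scene(shape = c(20, 20), n_years = 3, mparams = NULL,
                           seed = 3)
  ko <- knockout_random(sc$day, 0.10, seed = 13)
  res <- gapfill_cube(ko$cube, sc$dem)
  clim <- impute_climatology(ko$cube)
  rmse <- function(pred) sqrt(mean((pred - ko$truth)^2, na.rm = TRUE))
  expect_lte(rmse(res$mean$values[ko$deleted]), rmse(clim$values[ko$deleted]))
})

test_that("noise-free linear fields are recovered to machine-level accuracy", {
  sc <- linear_scene(shape = c(14, 14), n_years = 2)
  ko <- knockout_random(sc$day, 0.15, seed = 17)
  res <- gapfill_cube(ko$cube, sc$dem)
  err <- res$mean$values[ko$deleted] - ko$truth
  expect_lt(sqrt(mean(err^2)), 1e-6)
})

test_that("ineligible cubes are refused", {
  sc <- linear_scene(shape = c(12, 12), n_years = 1)
  cube <- sc$day
  land3 <- array(cube$land_mask, dim(cube$values))
  idx <- which(land3)
  set.seed(2)
  cube$values[sample(idx, round(0.6 * length(idx)))] <- NA
  expect_error(gapfill_cube(cube, sc$dem), "ineligible")
})
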