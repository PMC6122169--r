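# Per-island summary statistics (the shape of the published summary
# table) and report serialization.

#' Summarize a gap-filled island (day + night)
#'
#' Mean LST is the land average of each cell's temporal mean of the
#' observed (un-filled) cube; the LST range is the max - min of that
#' per-cell temporal-mean layer (a thermal-heterogeneity proxy); absolute
#' max/min pool the day and night observed extremes (per-photoperiod
#' extremes are also reported); availability is given pre gap-fill (obs
#' cube) and post gap-fill (mean cube, failures still missing).
#'
#' @param day,night [gapfill_cube()] results for the two photoperiods.
#' @param island Island name.
#' @param region Optional biogeographic region string.
#' @param notes Optional notes string.
#' @return A one-row data.frame of class `island_summary`.
#' @export
island_summary <- function(day, night, island = "island", region = NA_character_,
                           notes = "") {
  stopifnot(inherits(day, "gapfill_result"), inherits(night, "gapfill_result"))
  cell_stats <- function(res) {
    obs <- res$obs
    nl <- n_layers(obs)
    cnt <- rowSums(!is.na(obs$values), dims = 2)
    s <- rowSums(obs$values, dims = 2, na.rm = TRUE)
    cellmean <- ifelse(cnt > 0, s / cnt, NA_real_)
    cellmean[!obs$land_mask] <- NA_real_
    avail_pre <- 100 * sum(!is.na(obs$values[array(obs$land_mask, dim(obs$values))])) /
      (sum(obs$land_mask) * nl)
    avail_post <- 100 * sum(!is.na(res$mean$values[array(obs$land_mask, dim(obs$values))])) /
      (sum(obs$land_mask) * nl)
    list(mean = mean(cellmean, na.rm = TRUE),
         range = diff(range(cellmean, na.rm = TRUE)),
         obs_max = suppressWarnings(max(obs$values, na.rm = TRUE)),
         obs_min = suppressWarnings(min(obs$values, na.rm = TRUE)),
         avail_pre = avail_pre, avail_post = avail_post)
  }
  d <- cell_stats(day); n <- cell_stats(night)
  out <- data.frame(
    island = island, region = region,
    mean_lst_day = d$mean, mean_lst_night = n$mean,
    lst_range_day = d$range, lst_range_night = n$range,
    abs_max = max(d$obs_max, n$obs_max),
    abs_min = min(d$obs_min, n$obs_min),
    abs_max_day = d$obs_max, abs_min_day = d$obs_min,
    abs_max_night = n$obs_max, abs_min_night = n$obs_min,
    pct_available_day = d$avail_pre, pct_available_night = n$avail_pre,
    pct_available_post_day = d$avail_post,
    pct_available_post_night = n$avail_post,
    notes = notes, stringsAsFactors = FALSE)
  class(out) <- c("island_summary", class(out))
  out
}

#' Serialize a validation report to CSV + JSON
#'
#' Writes `table2_like.csv` (error statistics), `table3_like.csv`
#' (support-error fits, clustered mode) and `diagnostics.json` into a
#' directory. Output is byte-deterministic for fixed inputs.
#'
#' @param report A [run_validation_suite()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_validation_report <- function(report, dir) {
  stopifnot(inherits(report, "validation_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, "table2_like.csv")
  utils::write.csv(format_num_df(report$errors), paths[1], row.names = FALSE)
  if (!is.null(report$support_fits)) {
    p3 <- file.path(dir, "table3_like.csv")
    utils::write.csv(format_num_df(report$support_fits), p3, row.names = FALSE)
    paths <- c(paths, p3)
  }
  pj <- file.path(dir, "diagnostics.json")
  jsonlite::write_json(
    list(mode = report$mode, seed = report$seed,
         n_scenarios = nrow(report$errors)),
    pj, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, pj))
}

# round-trip-stable numeric formatting for deterministic CSVs
format_num_df <- function(df) {
  for (i in seq_along(df)) {
    if (is.numeric(df[[i]])) df[[i]] <- signif(df[[i]], 10)
  }
  df
}
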