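# Cube and DEM I/O plus the published file-naming convention.

#' Write an LST cube to disk
#'
#' NetCDF classic files carry one `lst` variable (degC, dimensions
#' `time x lat x lon`, time labelled by integer YYYYMM codes, standard
#' double fill value), CF-style coordinate variables, a byte `land_mask`
#' variable and WGS84 CRS metadata. GeoTIFF files are multi-page float64
#' stacks with YYYYMM band descriptions and EPSG:4326 geokeys (the land
#' mask is then inferred on re-read from cells observed at least once).
#'
#' @param cube An [lst_cube()].
#' @param path Output path.
#' @param format `"netcdf"` or `"geotiff"`; defaults from the file
#'   extension (`.nc` vs `.tif`/`.tiff`).
#' @return Invisibly, `path`.
#' @export
write_cube <- function(cube, path, format = c("auto", "netcdf", "geotiff")) {
  stopifnot(inherits(cube, "lst_cube"))
  format <- match.arg(format)
  if (format == "auto") format <- format_from_ext(path)
  co <- grid_coords(cube$grid)
  if (format == "netcdf") {
    vals <- cube$values
    vals[is.na(vals)] <- NC_FILL_DOUBLE
    nc_write(
      path,
      dims = list(time = n_layers(cube), lat = cube$grid$n_rows,
                  lon = cube$grid$n_cols),
      gatts = list(Conventions = "CF-1.6", crs = cube$grid$crs_id,
                   photoperiod = cube$photoperiod,
                   title = "monthly land surface temperature"),
      vars = list(
        list(name = "time", dims = 0L, type = "int",
             attrs = list(units = "YYYYMM", long_name = "year-month label"),
             data = cube$labels),
        list(name = "lat", dims = 1L, type = "double",
             attrs = list(units = "degrees_north"), data = co$lat),
        list(name = "lon", dims = 2L, type = "double",
             attrs = list(units = "degrees_east"), data = co$lon),
        list(name = "land_mask", dims = c(1L, 2L), type = "byte",
             attrs = list(long_name = "1 = land cell"),
             data = as.integer(t(cube$land_mask))),
        list(name = "lst", dims = c(0L, 1L, 2L), type = "double",
             attrs = list(units = "degrees_Celsius",
                          `_FillValue` = NC_FILL_DOUBLE,
                          long_name = "land surface temperature"),
             data = as.vector(aperm(vals, c(2L, 1L, 3L))))))
  } else if (format == "geotiff") {
    tif_write(path, cube$values, sprintf("%06d", cube$labels), cube$grid)
  } else {
    stop("unsupported format: ", format)
  }
  invisible(path)
}

format_from_ext <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext, nc = "netcdf", tif = , tiff = "geotiff",
         stop("cannot infer format from extension '.", ext,
              "'; pass format = explicitly"))
}

#' Read an LST cube from disk
#'
#' Accepts NetCDF classic or GeoTIFF files written by [write_cube()] (and
#' compliant files following the same layout). Layers are ordered
#' ascending by YYYYMM label; the fill value is normalized back to `NA`.
#'
#' @param path Input path.
#' @param photoperiod `"Day"` or `"Night"`; defaults to the value stored
#'   in the file, and must be given for files that carry none.
#' @return An [lst_cube()].
#' @export
read_cube <- function(path, photoperiod = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  magic <- readBin(path, "raw", n = 3L)
  if (rawToChar(magic) == "CDF") {
    f <- nc_read(path)
    v <- f$vars$lst
    if (is.null(v)) stop("no 'lst' variable in ", path)
    labels <- as.integer(f$vars$time$data)
    nlat <- f$dims[["lat"]]; nlon <- f$dims[["lon"]]
    vals <- aperm(array(v$data, c(nlon, nlat, length(labels))), c(2L, 1L, 3L))
    fill <- if (!is.null(v$attrs$`_FillValue`)) v$attrs$`_FillValue`
            else NC_FILL_DOUBLE
    vals[abs(vals - fill) <= abs(fill) * 1e-7] <- NA_real_
    lat <- f$vars$lat$data; lon <- f$vars$lon$data
    res <- if (nlon > 1) lon[2] - lon[1] else if (nlat > 1) lat[1] - lat[2] else 0.0083
    grid <- grid_meta(nlat, nlon, origin_lon = lon[1], origin_lat = lat[1],
                      resolution = res)
    lm <- if (!is.null(f$vars$land_mask)) {
      t(matrix(f$vars$land_mask$data == 1L, nlon, nlat))
    } else {
      rowSums(!is.na(vals), dims = 2) > 0
    }
    pp <- photoperiod %||%
      (if (!is.null(f$gatts$photoperiod)) f$gatts$photoperiod else
         stop("file stores no photoperiod; pass photoperiod ="))
    ord <- order(labels)
    lst_cube(grid, vals[, , ord, drop = FALSE], check_ym_labels(labels[ord]),
             pp, lm)
  } else {
    tf <- tif_read(path)
    labels <- suppressWarnings(as.integer(tf$labels))
    if (any(is.na(labels))) stop("GeoTIFF bands lack YYYYMM descriptions")
    res <- if (!is.null(tf$pixel_scale)) tf$pixel_scale[1] else 0.0083
    origin <- if (!is.null(tf$tiepoint)) tf$tiepoint[4:5] else c(0, 0)
    grid <- grid_meta(dim(tf$bands)[1], dim(tf$bands)[2],
                      origin_lon = origin[1], origin_lat = origin[2],
                      resolution = res)
    vals <- tf$bands
    vals[is.nan(vals)] <- NA_real_
    lm <- rowSums(!is.na(vals), dims = 2) > 0
    if (is.null(photoperiod)) stop("GeoTIFF stores no photoperiod; pass photoperiod =")
    ord <- order(labels)
    lst_cube(grid, vals[, , ord, drop = FALSE], check_ym_labels(labels[ord]),
             photoperiod, lm)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a DEM as a single-band GeoTIFF
#'
#' @param dem A [dem_grid()].
#' @param path File path.
#' @return `write_dem()` returns the path invisibly; `read_dem()` a
#'   [dem_grid()].
#' @export
write_dem <- function(dem, path) {
  stopifnot(inherits(dem, "dem_grid"))
  tif_write(path, dem$elevation, "elevation_m", dem$grid)
  invisible(path)
}

#' @rdname write_dem
#' @export
read_dem <- function(path) {
  tf <- tif_read(path)
  res <- if (!is.null(tf$pixel_scale)) tf$pixel_scale[1] else 0.0083
  origin <- if (!is.null(tf$tiepoint)) tf$tiepoint[4:5] else c(0, 0)
  grid <- grid_meta(dim(tf$bands)[1], dim(tf$bands)[2],
                    origin_lon = origin[1], origin_lat = origin[2],
                    resolution = res)
  dem_grid(grid, tf$bands[, , 1])
}

#' Output file name under the published naming convention
#'
#' `<island>_<photoperiod>_1km_mon_<dtype>.<ext>`, e.g.
#' `Marion_Day_1km_mon_mean.nc`.
#'
#' @param island Island name.
#' @param photoperiod `"Day"` or `"Night"`.
#' @param dtype One of `"mean"`, `"upperCI"`, `"lowerCI"`, `"obs"`.
#' @param ext File extension without the dot (e.g. `"nc"`, `"tif"`).
#' @return The file name string.
#' @export
output_name <- function(island, photoperiod, dtype, ext = "nc") {
  if (!all(photoperiod %in% c("Day", "Night"))) {
    stop("unknown photoperiod: ",
         paste(setdiff(photoperiod, c("Day", "Night")), collapse = ", "))
  }
  if (!all(dtype %in% c("mean", "upperCI", "lowerCI", "obs"))) {
    stop("unknown data type: ",
         paste(setdiff(dtype, c("mean", "upperCI", "lowerCI", "obs")),
               collapse = ", "))
  }
  sprintf("%s_%s_1km_mon_%s.%s", island, photoperiod, dtype, ext)
}
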