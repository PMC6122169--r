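# Minimal GeoTIFF writer/reader: little-endian classic TIFF, one IFD per
# band (multi-page), uncompressed 64-bit IEEE floating point samples, one
# strip per band. Band labels (YYYYMM) travel in ImageDescription; the
# first page carries ModelPixelScale/ModelTiepoint and a GeoKey directory
# declaring EPSG:4326 with the cell-centre (PixelIsPoint) convention.
# Only files following this layout (plus single-strip variants) are read.

TIFF_SHORT <- 3L; TIFF_LONG <- 4L; TIFF_ASCII <- 2L; TIFF_DOUBLE <- 12L
TIFF_TYPE_SIZE <- c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L)

tif_entry <- function(tag, type, values) {
  list(tag = as.integer(tag), type = as.integer(type), values = values)
}

tif_value_bytes <- function(e) {
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  if (e$type == TIFF_ASCII) {
    writeBin(c(charToRaw(e$values), as.raw(0L)), con)   # NUL-terminated
  } else if (e$type == TIFF_DOUBLE) {
    writeBin(as.numeric(e$values), con, size = 8, endian = "little")
  } else {
    writeBin(as.integer(e$values), con,
             size = TIFF_TYPE_SIZE[e$type], endian = "little")
  }
  rawConnectionValue(con)
}

#' Write a multi-band GeoTIFF
#'
#' @param path Output path.
#' @param bands Numeric array `n_rows x n_cols x n_bands` (NA allowed; NA
#'   is stored as IEEE NaN).
#' @param labels Character band descriptions (e.g. YYYYMM codes).
#' @param grid A [grid_meta()] providing the georeferencing.
#' @return Invisibly, the path.
#' @keywords internal
tif_write <- function(path, bands, labels, grid) {
  bands <- as.array(bands)
  if (length(dim(bands)) == 2L) dim(bands) <- c(dim(bands), 1L)
  nr <- dim(bands)[1]; nc <- dim(bands)[2]; nb <- dim(bands)[3]
  stopifnot(length(labels) == nb)
  band_bytes <- nr * nc * 8L
  geokeys <- c(1L, 1L, 0L, 3L,
               1024L, 0L, 1L, 2L,     # GTModelType: geographic
               1025L, 0L, 1L, 2L,     # GTRasterType: PixelIsPoint
               2048L, 0L, 1L, 4326L)  # GeographicType: WGS84
  ifds <- vector("list", nb)
  for (b in seq_len(nb)) {
    desc <- as.character(labels[b])
    entries <- list(
      tif_entry(256, TIFF_LONG, nc),
      tif_entry(257, TIFF_LONG, nr),
      tif_entry(258, TIFF_SHORT, 64L),
      tif_entry(259, TIFF_SHORT, 1L),
      tif_entry(262, TIFF_SHORT, 1L),
      tif_entry(270, TIFF_ASCII, desc),
      tif_entry(273, TIFF_LONG, 0L),       # strip offset, patched below
      tif_entry(277, TIFF_SHORT, 1L),
      tif_entry(278, TIFF_LONG, nr),
      tif_entry(279, TIFF_LONG, band_bytes),
      tif_entry(284, TIFF_SHORT, 1L),
      tif_entry(339, TIFF_SHORT, 3L))
    if (b == 1L) {
      entries <- c(entries, list(
        tif_entry(33550, TIFF_DOUBLE,
                  c(grid$resolution, grid$resolution, 0)),
        tif_entry(33922, TIFF_DOUBLE,
                  c(0, 0, 0, grid$origin_lon, grid$origin_lat, 0)),
        tif_entry(34735, TIFF_SHORT, geokeys)))
    }
    entries <- entries[order(vapply(entries, `[[`, integer(1), "tag"))]
    ifds[[b]] <- entries
  }
  # layout: header (8) | band data | aux values | IFDs
  data_start <- 8L
  aux_start <- data_start + nb * band_bytes
  aux <- raw(0)
  aux_offsets <- list()
  for (b in seq_len(nb)) {
    for (i in seq_along(ifds[[b]])) {
      e <- ifds[[b]][[i]]
      vb <- tif_value_bytes(e)
      if (length(vb) > 4L) {
        if (length(aux) %% 2L) aux <- c(aux, raw(1))
        aux_offsets[[paste(b, e$tag)]] <- aux_start + length(aux)
        aux <- c(aux, vb)
      }
    }
  }
  ifd_start <- aux_start + length(aux)
  if (ifd_start %% 2L) { aux <- c(aux, raw(1)); ifd_start <- ifd_start + 1L }
  ifd_size <- function(entries) 2L + 12L * length(entries) + 4L
  ifd_offsets <- ifd_start +
    cumsum(c(0L, vapply(ifds[-nb], ifd_size, numeric(1))))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(ifd_offsets[1]), con, size = 4, endian = "little")
  for (b in seq_len(nb)) {
    writeBin(as.numeric(t(bands[, , b])), con, size = 8, endian = "little")
  }
  writeBin(aux, con)
  for (b in seq_len(nb)) {
    entries <- ifds[[b]]
    writeBin(length(entries), con, size = 2, endian = "little")
    for (e in entries) {
      if (e$tag == 273L) e$values <- data_start + (b - 1L) * band_bytes
      vb <- tif_value_bytes(e)
      count <- if (e$type == TIFF_ASCII) length(vb) else length(e$values)
      writeBin(e$tag, con, size = 2, endian = "little")
      writeBin(e$type, con, size = 2, endian = "little")
      writeBin(as.integer(count), con, size = 4, endian = "little")
      if (length(vb) > 4L) {
        writeBin(as.integer(aux_offsets[[paste(b, e$tag)]]), con,
                 size = 4, endian = "little")
      } else {
        writeBin(c(vb, raw(4L - length(vb))), con)
      }
    }
    nxt <- if (b < nb) as.integer(ifd_offsets[b + 1]) else 0L
    writeBin(nxt, con, size = 4, endian = "little")
  }
  invisible(path)
}

tif_read_values <- function(raw_bytes, type, count, field) {
  sz <- TIFF_TYPE_SIZE[type]
  bytes <- if (count * sz <= 4L) {
    field[seq_len(count * sz)]
  } else {
    off <- readBin(field, "integer", size = 4, endian = "little")
    raw_bytes[(off + 1L):(off + count * sz)]
  }
  switch(as.character(type),
    "2" = rawToChar(bytes[bytes != as.raw(0L)]),
    "3" = readBin(bytes, "integer", n = count, size = 2,
                  endian = "little", signed = FALSE),
    "4" = readBin(bytes, "integer", n = count, size = 4, endian = "little"),
    "12" = readBin(bytes, "numeric", n = count, size = 8, endian = "little"),
    stop("unsupported TIFF field type ", type))
}

#' Read a GeoTIFF written by [tif_write()]
#'
#' @param path File path.
#' @return List with `bands` (array rows x cols x n), `labels`,
#'   `pixel_scale`, `tiepoint`, `epsg`.
#' @keywords internal
tif_read <- function(path) {
  raw_bytes <- readBin(path, "raw", n = file.size(path))
  if (rawToChar(raw_bytes[1:2]) != "II" ||
      readBin(raw_bytes[3:4], "integer", size = 2, endian = "little") != 42L) {
    stop("not a little-endian classic TIFF: ", path)
  }
  ifd_off <- readBin(raw_bytes[5:8], "integer", size = 4, endian = "little")
  pages <- list(); labels <- character(0)
  pixel_scale <- NULL; tiepoint <- NULL; epsg <- NA_integer_
  first <- TRUE
  while (ifd_off != 0L) {
    n_entries <- readBin(raw_bytes[ifd_off + 1:2], "integer", size = 2,
                         endian = "little")
    tags <- list()
    for (i in seq_len(n_entries)) {
      base <- ifd_off + 2L + (i - 1L) * 12L
      tag <- readBin(raw_bytes[base + 1:2], "integer", size = 2,
                     endian = "little", signed = FALSE)
      type <- readBin(raw_bytes[base + 3:4], "integer", size = 2,
                      endian = "little")
      count <- readBin(raw_bytes[base + 5:8], "integer", size = 4,
                       endian = "little")
      tags[[as.character(tag)]] <-
        tif_read_values(raw_bytes, type, count, raw_bytes[base + 9:12])
    }
    need <- c("256", "257", "258", "273", "279", "339")
    if (!all(need %in% names(tags))) stop("TIFF page missing required tags")
    if (!identical(as.integer(tags[["258"]]), 64L) ||
        !identical(as.integer(tags[["339"]]), 3L)) {
      stop("only 64-bit IEEE float TIFF samples are supported")
    }
    if (!is.null(tags[["259"]]) && as.integer(tags[["259"]]) != 1L) {
      stop("compressed TIFFs are not supported")
    }
    nc <- as.integer(tags[["256"]]); nr <- as.integer(tags[["257"]])
    offs <- as.numeric(tags[["273"]]); cnts <- as.numeric(tags[["279"]])
    vals <- numeric(0)
    for (s in seq_along(offs)) {
      b <- raw_bytes[(offs[s] + 1):(offs[s] + cnts[s])]
      vals <- c(vals, readBin(b, "numeric", n = cnts[s] / 8, size = 8,
                              endian = "little"))
    }
    pages[[length(pages) + 1L]] <- matrix(vals, nr, nc, byrow = TRUE)
    labels <- c(labels, if (is.null(tags[["270"]])) NA_character_
                        else tags[["270"]])
    if (first) {
      pixel_scale <- tags[["33550"]]
      tiepoint <- tags[["33922"]]
      gk <- tags[["34735"]]
      if (!is.null(gk)) {
        keys <- matrix(gk[-(1:4)], ncol = 4, byrow = TRUE)
        hit <- keys[keys[, 1] == 2048, , drop = FALSE]
        if (nrow(hit)) epsg <- as.integer(hit[1, 4])
      }
      first <- FALSE
    }
    ifd_off <- readBin(raw_bytes[ifd_off + 2L + n_entries * 12L + 1:4],
                       "integer", size = 4, endian = "little")
  }
  bands <- array(unlist(pages), c(nrow(pages[[1]]), ncol(pages[[1]]),
                                  length(pages)))
  list(bands = bands, labels = labels, pixel_scale = pixel_scale,
       tiepoint = tiepoint, epsg = epsg)
}
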