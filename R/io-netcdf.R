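# Minimal NetCDF classic-format (CDF-1) writer/reader.
#
# Only the subset needed for LST cubes is supported: fixed (non-record)
# dimensions, NC_BYTE/CHAR/SHORT/INT/FLOAT/DOUBLE data, and flat
# attribute lists. Files written here are valid classic NetCDF and are
# read by any compliant library (scipy.io.netcdf_file is used as the
# round-trip oracle in the tests). All multi-byte values are big-endian.

NC_TYPES <- c(byte = 1L, char = 2L, short = 3L, int = 4L,
              float = 5L, double = 6L)
NC_SIZE <- c(1L, 1L, 2L, 4L, 4L, 8L)
NC_FILL_DOUBLE <- 9.969209968386869e36

pad4 <- function(n) (4L - (n %% 4L)) %% 4L

nc_put_name <- function(con, name) {
  b <- charToRaw(name)
  writeBin(length(b), con, size = 4, endian = "big")
  writeBin(b, con)
  writeBin(raw(pad4(length(b))), con)
}

nc_put_values <- function(con, type, values) {
  if (type == NC_TYPES[["char"]]) {
    b <- charToRaw(paste0(values, collapse = ""))
    writeBin(length(b), con, size = 4, endian = "big")
    writeBin(b, con)
    writeBin(raw(pad4(length(b))), con)
  } else {
    writeBin(length(values), con, size = 4, endian = "big")
    sz <- NC_SIZE[type]
    if (type == NC_TYPES[["double"]] || type == NC_TYPES[["float"]]) {
      writeBin(as.numeric(values), con, size = sz, endian = "big")
    } else {
      writeBin(as.integer(values), con, size = sz, endian = "big")
    }
    writeBin(raw(pad4(length(values) * sz)), con)
  }
}

nc_put_attrs <- function(con, attrs) {
  if (!length(attrs)) {
    writeBin(c(0L, 0L), con, size = 4, endian = "big")
    return(invisible())
  }
  writeBin(c(12L, length(attrs)), con, size = 4, endian = "big")  # NC_ATTRIBUTE
  for (nm in names(attrs)) {
    a <- attrs[[nm]]
    type <- if (is.character(a)) NC_TYPES[["char"]]
            else if (is.integer(a)) NC_TYPES[["int"]]
            else NC_TYPES[["double"]]
    nc_put_name(con, nm)
    writeBin(as.integer(type), con, size = 4, endian = "big")
    nc_put_values(con, type, a)
  }
}

# vars: list of list(name, dims = integer dim ids (0-based, slowest first),
#                    type, attrs, data)
nc_serialize_header <- function(dims, gatts, vars, begins) {
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(charToRaw("CDF"), con)
  writeBin(as.raw(1L), con)                       # CDF-1
  writeBin(0L, con, size = 4, endian = "big")     # numrecs
  writeBin(c(10L, length(dims)), con, size = 4, endian = "big")  # NC_DIMENSION
  for (nm in names(dims)) {
    nc_put_name(con, nm)
    writeBin(as.integer(dims[[nm]]), con, size = 4, endian = "big")
  }
  nc_put_attrs(con, gatts)
  writeBin(c(11L, length(vars)), con, size = 4, endian = "big")  # NC_VARIABLE
  for (i in seq_along(vars)) {
    v <- vars[[i]]
    nc_put_name(con, v$name)
    writeBin(length(v$dims), con, size = 4, endian = "big")
    if (length(v$dims)) {
      writeBin(as.integer(v$dims), con, size = 4, endian = "big")
    }
    nc_put_attrs(con, v$attrs)
    writeBin(as.integer(v$type), con, size = 4, endian = "big")
    writeBin(as.integer(nc_vsize(v, dims)), con, size = 4, endian = "big")
    writeBin(as.integer(begins[i]), con, size = 4, endian = "big")
  }
  rawConnectionValue(con)
}

nc_vsize <- function(v, dims) {
  n <- prod(vapply(v$dims, function(d) dims[[d + 1L]], numeric(1)))
  raw_n <- n * NC_SIZE[v$type]
  as.integer(raw_n + pad4(raw_n))
}

#' Write a classic NetCDF file
#'
#' Low-level writer used by [write_cube()]; exposed for completeness.
#'
#' @param path Output file path.
#' @param dims Named list/vector of dimension sizes, in definition order.
#' @param gatts Named list of global attributes.
#' @param vars List of variables: each a list with `name`, `dims`
#'   (0-based dimension ids, slowest-varying first), `type` (a name in
#'   `c("byte","char","short","int","float","double")`), `attrs`, and
#'   `data` (numeric vector in row-major order of `dims`).
#' @return Invisibly, the path.
#' @keywords internal
nc_write <- function(path, dims, gatts, vars) {
  for (i in seq_along(vars)) {
    vars[[i]]$type <- NC_TYPES[[vars[[i]]$type]]
  }
  header0 <- nc_serialize_header(dims, gatts, vars, rep(0L, length(vars)))
  begins <- integer(length(vars))
  off <- length(header0)
  for (i in seq_along(vars)) {
    begins[i] <- off
    off <- off + nc_vsize(vars[[i]], dims)
  }
  header <- nc_serialize_header(dims, gatts, vars, begins)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(header, con)
  for (v in vars) {
    nbytes_pad <- nc_vsize(v, dims)
    sz <- NC_SIZE[v$type]
    n <- nbytes_pad %/% sz   # may exceed length(data) by the pad
    if (v$type == NC_TYPES[["char"]]) {
      b <- charToRaw(paste0(v$data, collapse = ""))
      writeBin(b, con)
      writeBin(raw(nbytes_pad - length(b)), con)
    } else if (v$type %in% NC_TYPES[c("float", "double")]) {
      writeBin(as.numeric(v$data), con, size = sz, endian = "big")
      writeBin(raw(nbytes_pad - length(v$data) * sz), con)
    } else {
      writeBin(as.integer(v$data), con, size = sz, endian = "big")
      writeBin(raw(nbytes_pad - length(v$data) * sz), con)
    }
  }
  invisible(path)
}

# --- reader ---------------------------------------------------------------

nc_reader_env <- function(raw_bytes) {
  e <- new.env()
  e$raw <- raw_bytes
  e$pos <- 1L
  e
}

nc_take <- function(e, n) {
  out <- e$raw[e$pos:(e$pos + n - 1L)]
  e$pos <- e$pos + as.integer(n)
  out
}

nc_int <- function(e, n = 1L) {
  readBin(nc_take(e, 4L * n), "integer", n = n, size = 4, endian = "big")
}

nc_name <- function(e) {
  len <- nc_int(e)
  nm <- rawToChar(nc_take(e, len))
  if (pad4(len)) nc_take(e, pad4(len))
  nm
}

nc_read_values <- function(e, type, n) {
  sz <- NC_SIZE[type]
  bytes <- nc_take(e, n * sz)
  out <- switch(as.character(type),
    "1" = readBin(bytes, "integer", n = n, size = 1, signed = TRUE),
    "2" = rawToChar(bytes),
    "3" = readBin(bytes, "integer", n = n, size = 2, endian = "big"),
    "4" = readBin(bytes, "integer", n = n, size = 4, endian = "big"),
    "5" = readBin(bytes, "numeric", n = n, size = 4, endian = "big"),
    "6" = readBin(bytes, "numeric", n = n, size = 8, endian = "big"),
    stop("unsupported NetCDF type ", type))
  if (pad4(n * sz)) nc_take(e, pad4(n * sz))
  out
}

nc_read_attrs <- function(e) {
  tag <- nc_int(e); n <- nc_int(e)
  if (tag == 0L && n == 0L) return(list())
  if (tag != 12L) stop("malformed NetCDF attribute list")
  out <- list()
  for (i in seq_len(n)) {
    nm <- nc_name(e)
    type <- nc_int(e)
    cnt <- nc_int(e)
    out[[nm]] <- nc_read_values(e, type, cnt)
  }
  out
}

#' Read a classic NetCDF file
#'
#' @param path File path (CDF-1 or CDF-2, non-record variables only).
#' @return List with `dims`, `gatts` and `vars`; each variable carries
#'   `dims` (sizes, slowest first), `attrs` and `data`.
#' @keywords internal
nc_read <- function(path) {
  raw_bytes <- readBin(path, "raw", n = file.size(path))
  e <- nc_reader_env(raw_bytes)
  magic <- rawToChar(nc_take(e, 3L))
  version <- as.integer(nc_take(e, 1L))
  if (magic != "CDF" || !version %in% c(1L, 2L)) {
    stop("not a classic NetCDF file: ", path)
  }
  numrecs <- nc_int(e)
  tag <- nc_int(e); ndims <- nc_int(e)
  dims <- integer(0)
  if (tag == 10L) {
    for (i in seq_len(ndims)) {
      nm <- nc_name(e)
      dims[nm] <- nc_int(e)
    }
  } else if (!(tag == 0L && ndims == 0L)) stop("malformed dimension list")
  if (any(dims == 0L)) stop("record (unlimited) dimensions are not supported")
  gatts <- nc_read_attrs(e)
  tag <- nc_int(e); nvars <- nc_int(e)
  vars <- list()
  if (tag == 11L) {
    offsize <- if (version == 2L) 8L else 4L
    for (i in seq_len(nvars)) {
      nm <- nc_name(e)
      nd <- nc_int(e)
      dimids <- if (nd) nc_int(e, nd) else integer(0)
      attrs <- nc_read_attrs(e)
      type <- nc_int(e)
      vsize <- nc_int(e)
      begin <- if (version == 2L) {
        b <- readBin(nc_take(e, 8L), "integer", n = 2, size = 4, endian = "big")
        b[1] * 2^32 + (b[2] %% 2^32)
      } else nc_int(e)
      vars[[nm]] <- list(dimids = dimids, attrs = attrs, type = type,
                         begin = begin)
    }
  } else if (!(tag == 0L && nvars == 0L)) stop("malformed variable list")
  for (nm in names(vars)) {
    v <- vars[[nm]]
    sizes <- unname(dims[v$dimids + 1L])
    n <- prod(sizes)
    e$pos <- as.integer(v$begin) + 1L
    vars[[nm]]$data <- nc_read_values(e, v$type, n)
    vars[[nm]]$dims <- sizes
  }
  list(dims = dims, gatts = gatts, vars = vars)
}
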