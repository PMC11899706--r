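#' Read and write NRRD volumes
#'
#' Minimal reader/writer for the "nearly raw raster data" (NRRD) format used
#' to store anonymized OCT volumes and their ROI masks: a text header
#' (magic `NRRD000x`, `field: value` lines, blank line) followed by the voxel
#' payload. Supported payload encodings are `raw` (little or big endian),
#' `ascii`/`text` and `gzip`; supported types cover the common integer and
#' float widths. Voxel spacing is taken from `spacings` or from the row norms
#' of `space directions`; a header carrying neither is rejected, as physical
#' spacing is required by shape features.
#'
#' @param path File path.
#' @return [read_nrrd()] returns an [oct_volume()]; [read_mask()] returns an
#'   [oct_mask()] (any non-zero voxel becomes foreground).
#' @examples
#' f <- tempfile(fileext = ".nrrd")
#' vol <- oct_volume(array(1:24 %% 256, c(4, 3, 2)), spacing = c(0.05, 0.05, 0.1))
#' write_nrrd(vol, f)
#' identical(read_nrrd(f)$values, vol$values)
#' @export
read_nrrd <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (!grepl("^NRRD000", magic)) abort(sprintf("not an NRRD file: %s", path))
  fields <- list()
  repeat {
    line <- read_header_line(con)
    if (is.null(line) || line == "") break
    if (grepl("^#", line)) next
    m <- regmatches(line, regexec("^([^:]+):[=]? ?(.*)$", line))[[1]]
    if (length(m) == 3L) fields[[tolower(trimws(m[2]))]] <- trimws(m[3])
  }
  dim_n <- as.integer(fields[["dimension"]] %||% abort("NRRD header lacks 'dimension'"))
  sizes <- as.integer(strsplit(fields[["sizes"]] %||% abort("NRRD header lacks 'sizes'"),
                               "[[:space:]]+")[[1]])
  if (dim_n != 3L || length(sizes) != 3L) {
    abort(sprintf("expected a 3D NRRD payload, got dimension %d", dim_n))
  }
  spacing <- nrrd_spacing(fields)
  origin <- nrrd_origin(fields)
  type <- nrrd_type(fields[["type"]] %||% abort("NRRD header lacks 'type'"))
  encoding <- tolower(fields[["encoding"]] %||% "raw")
  n <- prod(sizes)
  values <- switch(encoding,
    raw = {
      endian <- if (identical(fields[["endian"]], "big")) "big" else "little"
      readBin(con, what = type$what, n = n, size = type$size,
              signed = type$signed, endian = endian)
    },
    ascii = , text = , txt = {
      scan(con, what = double(), n = n, quiet = TRUE)
    },
    gzip = , gz = {
      comp <- readBin(con, what = "raw", n = file.size(path))
      payload <- memDecompress(comp, type = "gzip")
      endian <- if (identical(fields[["endian"]], "big")) "big" else "little"
      readBin(payload, what = type$what, n = n, size = type$size,
              signed = type$signed, endian = endian)
    },
    abort(sprintf("unsupported NRRD encoding: %s", encoding))
  )
  if (length(values) != n) abort("NRRD payload shorter than header 'sizes' promise")
  arr <- array(as.numeric(values), dim = sizes)
  oct_volume(clamp255(arr), spacing = spacing, origin = origin)
}

#' @rdname read_nrrd
#' @export
read_mask <- function(path) {
  v <- read_nrrd(path)
  oct_mask(v$values != 0, spacing = v$spacing, origin = v$origin)
}

#' @rdname read_nrrd
#' @param volume An [oct_volume()] or [oct_mask()] to write.
#' @param encoding One of `"raw"` (uint8, little endian), `"ascii"`, `"gzip"`.
#' @export
write_nrrd <- function(volume, path, encoding = c("raw", "ascii", "gzip")) {
  encoding <- match.arg(encoding)
  stopifnot(inherits(volume, "oct_volume") || inherits(volume, "oct_mask"))
  vals <- round(volume$values)
  if (min(vals) < 0 || max(vals) > 255) abort("NRRD writer stores 8-bit data in [0, 255]")
  d <- dim(vals)
  hdr <- c("NRRD0004",
           "# generated by octradiomics",
           "type: unsigned char",
           "dimension: 3",
           sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
           sprintf("spacings: %.10g %.10g %.10g",
                   volume$spacing[1], volume$spacing[2], volume$spacing[3]),
           sprintf("space origin: (%.10g,%.10g,%.10g)",
                   volume$origin[1], volume$origin[2], volume$origin[3]),
           if (encoding == "raw") "endian: little",
           sprintf("encoding: %s", encoding),
           "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  bytes <- as.raw(as.integer(vals))
  switch(encoding,
    raw = writeBin(bytes, con),
    ascii = writeLines(paste(as.integer(vals), collapse = " "), con),
    gzip = writeBin(memCompress(bytes, type = "gzip"), con))
  invisible(path)
}

# read one header text line from a binary connection (stop at \n)
read_header_line <- function(con) {
  out <- raw(0)
  repeat {
    ch <- readBin(con, what = "raw", n = 1L)
    if (length(ch) == 0L) return(if (length(out)) rawToChar(out) else NULL)
    if (ch == as.raw(10L)) return(sub("\r$", "", rawToChar(out)))
    out <- c(out, ch)
  }
}

nrrd_spacing <- function(fields) {
  if (!is.null(fields[["spacings"]])) {
    sp <- as.numeric(strsplit(fields[["spacings"]], "[[:space:]]+")[[1]])
    if (length(sp) != 3L || any(!is.finite(sp)) || any(sp <= 0)) {
      abort("invalid 'spacings' in NRRD header")
    }
    return(sp)
  }
  if (!is.null(fields[["space directions"]])) {
    rows <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    sp <- vapply(rows, function(r) {
      v <- as.numeric(strsplit(gsub("[()]", "", r), ",")[[1]])
      sqrt(sum(v^2))
    }, numeric(1))
    if (length(sp) != 3L || any(!is.finite(sp)) || any(sp <= 0)) {
      abort("invalid 'space directions' in NRRD header")
    }
    return(unname(sp))
  }
  abort("NRRD header carries neither 'spacings' nor 'space directions'")
}

nrrd_origin <- function(fields) {
  so <- fields[["space origin"]]
  if (is.null(so)) return(c(0, 0, 0))
  v <- as.numeric(strsplit(gsub("[()]", "", so), ",")[[1]])
  if (length(v) != 3L || any(!is.finite(v))) return(c(0, 0, 0))
  v
}

nrrd_type <- function(type) {
  switch(tolower(type),
    "uchar" = , "unsigned char" = , "uint8" = , "uint8_t" =
      list(what = "integer", size = 1L, signed = FALSE),
    "char" = , "signed char" = , "int8" = , "int8_t" =
      list(what = "integer", size = 1L, signed = TRUE),
    "short" = , "int16" = , "int16_t" = list(what = "integer", size = 2L, signed = TRUE),
    "ushort" = , "uint16" = , "unsigned short" = , "uint16_t" =
      list(what = "integer", size = 2L, signed = FALSE),
    "int" = , "int32" = , "int32_t" = list(what = "integer", size = 4L, signed = TRUE),
    "uint" = , "uint32" = , "unsigned int" = , "uint32_t" =
      list(what = "integer", size = 4L, signed = TRUE),
    "float" = list(what = "double", size = 4L, signed = TRUE),
    "double" = list(what = "double", size = 8L, signed = TRUE),
    abort(sprintf("unsupported NRRD type: %s", type)))
}

clamp255 <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}
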