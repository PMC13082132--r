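# Minimal TIFF 6.0 codec for 32-bit IEEE float, single-sample, uncompressed,
# multi-page images (little-endian, one strip per page). Installed R TIFF
# bindings store integer-scaled samples clamped to [0, 1], which cannot
# round-trip scientific float data, so the pipeline's container format is
# implemented here directly.

TIFF_TAGS <- c(width = 256L, height = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, spp = 277L,
               rows_per_strip = 278L, strip_bytes = 279L,
               sample_format = 339L)

write_tiff_float <- function(pages, path) {
  if (is.array(pages) && length(dim(pages)) == 3L)
    pages <- lapply(seq_len(dim(pages)[3L]), function(i) pages[, , i])
  stopifnot(length(pages) >= 1L, all(vapply(pages, is.matrix, NA)))
  con <- file(path, "wb")
  on.exit(close(con))
  w <- function(x, size) writeBin(x, con, size = size, endian = "little")
  # header: "II", magic 42, offset of first IFD
  writeBin(charToRaw("II"), con)
  w(42L, 2L)
  n <- length(pages)
  ifd_size <- 2L + 10L * 12L + 4L
  # layout per page: [IFD][pixel data]; first IFD right after the header
  offsets <- integer(n)
  off <- 8L
  data_bytes <- vapply(pages, function(m) length(m) * 4L, 0L)
  for (i in seq_len(n)) {
    offsets[i] <- off
    off <- off + ifd_size + data_bytes[i]
  }
  w(offsets[1], 4L)
  entry <- function(tag, type, count, value) {
    w(tag, 2L); w(type, 2L); w(count, 4L)
    if (type == 3L) { w(value, 2L); w(0L, 2L) } else w(value, 4L)
  }
  for (i in seq_len(n)) {
    m <- pages[[i]]
    data_off <- offsets[i] + ifd_size
    w(10L, 2L)  # entry count
    entry(TIFF_TAGS[["width"]], 4L, 1L, ncol(m))
    entry(TIFF_TAGS[["height"]], 4L, 1L, nrow(m))
    entry(TIFF_TAGS[["bits"]], 3L, 1L, 32L)
    entry(TIFF_TAGS[["compression"]], 3L, 1L, 1L)
    entry(TIFF_TAGS[["photometric"]], 3L, 1L, 1L)
    entry(TIFF_TAGS[["strip_offsets"]], 4L, 1L, data_off)
    entry(TIFF_TAGS[["spp"]], 3L, 1L, 1L)
    entry(TIFF_TAGS[["rows_per_strip"]], 4L, 1L, nrow(m))
    entry(TIFF_TAGS[["strip_bytes"]], 4L, 1L, data_bytes[i])
    entry(TIFF_TAGS[["sample_format"]], 3L, 1L, 3L)  # IEEE float
    w(if (i < n) offsets[i + 1L] else 0L, 4L)
    # row-major pixel order
    writeBin(as.vector(t(m)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

read_tiff_float <- function(path) {
  raw_data <- readBin(path, "raw", n = file.info(path)$size)
  u16 <- function(off) sum(as.integer(raw_data[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.numeric(raw_data[off + 1:4]) *
                             c(1, 256, 65536, 16777216))
  if (rawToChar(raw_data[1:2]) != "II" || u16(2) != 42L)
    stop_invalid("not a little-endian TIFF file: %s", path)
  ifd <- u32(4)
  pages <- list()
  while (ifd != 0) {
    n_ent <- u16(ifd)
    tags <- list()
    for (e in seq_len(n_ent)) {
      base <- ifd + 2 + (e - 1) * 12
      tag <- u16(base); type <- u16(base + 2)
      val <- if (type == 3L) u16(base + 8) else u32(base + 8)
      tags[[as.character(tag)]] <- val
    }
    need <- function(tag) {
      v <- tags[[as.character(TIFF_TAGS[[tag]])]]
      if (is.null(v)) stop_invalid("TIFF page missing tag '%s'", tag)
      v
    }
    if (!is.null(tags[["259"]]) && tags[["259"]] != 1L)
      stop_invalid("compressed TIFF not supported")
    if (!is.null(tags[["339"]]) && tags[["339"]] != 3L)
      stop_invalid("only IEEE-float TIFF samples are supported")
    nx <- need("width"); ny <- need("height")
    off <- need("strip_offsets")
    vals <- readBin(raw_data[(off + 1):(off + 4 * nx * ny)], "double",
                    n = nx * ny, size = 4L, endian = "little")
    pages[[length(pages) + 1L]] <- matrix(vals, ny, nx, byrow = TRUE)
    ifd <- u32(ifd + 2 + n_ent * 12)
  }
  pages
}

# snap doubles to their nearest float32 representation
as_float32 <- function(x) {
  d <- dim(x)
  out <- readBin(writeBin(as.vector(x), raw(), size = 4L), "double",
                 n = length(x), size = 4L)
  dim(out) <- d
  out
}

#' Write an image stack as multi-page TIFF with CSV sidecar
#'
#' Pages are 32-bit float, ordered by ascending spectral band or time frame.
#' The axis always travels in the sidecar CSV (columns `page_index`
#' (0-based), `wavenumber_cm1` or `time_s`, and `pixel_size_nm`), never in
#' TIFF metadata. Data are stored at float32 precision; a write/read
#' round-trip is bit-exact for float32 data.
#'
#' @param stack a [hyperspectral_stack()] or [time_lapse_stack()].
#' @param path output TIFF path.
#' @param sidecar_path output CSV path (default: `path` with `.csv`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, sidecar_path = sidecar_of(path)) {
  np <- n_pages(stack)
  if (inherits(stack, "hyperspectral_stack")) {
    axis <- data.frame(page_index = seq_len(np) - 1L,
                       wavenumber_cm1 = stack$wavenumber,
                       pixel_size_nm = stack$pixel_size_nm)
  } else if (inherits(stack, "time_lapse_stack")) {
    axis <- data.frame(page_index = seq_len(np) - 1L,
                       time_s = (seq_len(np) - 1L) * stack$dt,
                       pixel_size_nm = stack$pixel_size_nm)
  } else stop_invalid("not a stack object")
  write_tiff_float(as_float32(stack$data), path)
  utils::write.csv(axis, sidecar_path, row.names = FALSE)
  invisible(path)
}

sidecar_of <- function(path) sub("\\.tiff?$", ".csv", path, ignore.case = TRUE)

#' Read an image stack from multi-page TIFF + CSV sidecar
#'
#' The axis type is inferred from the sidecar column: `wavenumber_cm1`
#' yields a [hyperspectral_stack()], `time_s` a [time_lapse_stack()] (with
#' `dt` from the first difference). Page count must equal the sidecar row
#' count.
#'
#' @param path TIFF path.
#' @param sidecar_path CSV sidecar path (default: `path` with `.csv`).
#' @return A stack object.
#' @export
read_stack <- function(path, sidecar_path = sidecar_of(path)) {
  if (!file.exists(sidecar_path))
    stop_invalid("missing sidecar CSV: %s", sidecar_path)
  axis <- utils::read.csv(sidecar_path)
  pages <- read_tiff_float(path)
  if (length(pages) != nrow(axis))
    stop_invalid("TIFF has %d pages but sidecar has %d rows",
                 length(pages), nrow(axis))
  cube <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  px <- if ("pixel_size_nm" %in% names(axis))
    as.numeric(axis$pixel_size_nm[1]) else 100
  if ("wavenumber_cm1" %in% names(axis)) {
    hyperspectral_stack(cube, as.numeric(axis$wavenumber_cm1), px)
  } else if ("time_s" %in% names(axis)) {
    dt <- if (nrow(axis) > 1L) as.numeric(diff(axis$time_s)[1]) else 1
    time_lapse_stack(cube, dt, px)
  } else {
    stop_invalid("sidecar must contain a wavenumber_cm1 or time_s column")
  }
}
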