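#' Hyperspectral image stack
#'
#' Container for a hyperspectral cube indexed `[y, x, band]` with a calibrated
#' wavenumber axis. This is the raw input of the spectral pipeline: each page
#' is an image of the field of view recorded at one Raman shift.
#'
#' @param data numeric array `[ny, nx, n_bands]`.
#' @param wavenumber numeric vector of band positions in cm^-1, strictly
#'   increasing, one entry per page.
#' @param pixel_size_nm physical pixel pitch in nm.
#' @param meta free-form named list of acquisition metadata.
#' @return An object of class `hyperspectral_stack`.
#' @seealso [time_lapse_stack()], [read_stack()], [write_stack()]
#' @export
hyperspectral_stack <- function(data, wavenumber, pixel_size_nm, meta = list()) {
  data <- as_cube(data)
  if (!is.numeric(wavenumber) || any(!is.finite(wavenumber)))
    stop_invalid("wavenumber axis must be finite numeric")
  if (length(wavenumber) != dim(data)[3L])
    stop_invalid("axis length (%d) != number of bands (%d)",
                 length(wavenumber), dim(data)[3L])
  if (length(wavenumber) > 1L && any(diff(wavenumber) <= 0))
    stop_invalid("wavenumber axis must be strictly increasing")
  check_number(pixel_size_nm, "pixel_size_nm", 0, strict_lower = TRUE)
  structure(list(data = data, wavenumber = as.numeric(wavenumber),
                 pixel_size_nm = pixel_size_nm, meta = meta),
            class = "hyperspectral_stack")
}

#' Time-lapse image stack
#'
#' Container for a movie indexed `[y, x, frame]` with a uniform frame
#' interval, used for landing assays, binding kinetics and conformational
#' switching experiments.
#'
#' @param data numeric array `[ny, nx, n_frames]` with at least 2 frames.
#' @param dt frame interval in seconds.
#' @inheritParams hyperspectral_stack
#' @return An object of class `time_lapse_stack`.
#' @export
time_lapse_stack <- function(data, dt, pixel_size_nm, meta = list()) {
  data <- as_cube(data)
  if (dim(data)[3L] < 2L) stop_invalid("a time-lapse stack needs >= 2 frames")
  check_number(dt, "dt", 0, strict_lower = TRUE)
  check_number(pixel_size_nm, "pixel_size_nm", 0, strict_lower = TRUE)
  structure(list(data = data, dt = dt,
                 pixel_size_nm = pixel_size_nm, meta = meta),
            class = "time_lapse_stack")
}

as_cube <- function(data) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_invalid("stack data must be a [y, x, page] array")
  storage.mode(data) <- "double"
  data
}

#' @export
print.hyperspectral_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hyperspectral_stack> %d x %d px, %d bands (%.0f-%.0f cm^-1), %g nm/px\n",
              d[2], d[1], d[3], min(x$wavenumber), max(x$wavenumber),
              x$pixel_size_nm))
  invisible(x)
}

#' @export
print.time_lapse_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<time_lapse_stack> %d x %d px, %d frames @ %g s, %g nm/px\n",
              d[2], d[1], d[3], x$dt, x$pixel_size_nm))
  invisible(x)
}

#' Number of pages in a stack
#' @param x a stack object.
#' @return integer page count.
#' @export
n_pages <- function(x) dim(x$data)[3L]

#' Single-molecule intensity time trace
#'
#' @param time numeric vector of frame times in seconds, uniformly spaced.
#' @param intensity numeric vector of per-frame intensities (detector units).
#' @param id optional spot identifier.
#' @return An object of class `intensity_trace` (data frame with columns
#'   `time_s`, `intensity` and attributes `dt`, `id`).
#' @export
intensity_trace <- function(time, intensity, id = NA_character_) {
  if (length(time) != length(intensity))
    stop_invalid("time and intensity lengths differ")
  if (length(time) < 2L) stop_invalid("a trace needs >= 2 frames")
  dts <- diff(time)
  if (any(abs(dts - dts[1]) > 1e-9 * max(abs(dts[1]), 1)))
    stop_invalid("trace times must be uniformly spaced")
  structure(data.frame(time_s = as.numeric(time),
                       intensity = as.numeric(intensity)),
            dt = dts[1], id = id,
            class = c("intensity_trace", "data.frame"))
}

trace_dt <- function(trace) attr(trace, "dt")

#' @export
plot.intensity_trace <- function(x, ...) {
  graphics::plot(x$time_s, x$intensity, type = "l",
                 xlab = "time (s)", ylab = "intensity (detector units)", ...)
  invisible(x)
}
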