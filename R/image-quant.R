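# Separable Gaussian smoothing with replicate (edge-clamped) padding.
gaussian_blur <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  half <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(-half:half, sd = sigma_px)
  k <- k / sum(k)
  smooth_rows <- function(m) {
    n <- ncol(m)
    idx <- outer(seq_len(n), -half:half, `+`)
    idx[idx < 1L] <- 1L; idx[idx > n] <- n
    out <- matrix(0, nrow(m), n)
    for (j in seq_along(k)) out <- out + m[, idx[, j], drop = FALSE] * k[j]
    out
  }
  t(smooth_rows(t(smooth_rows(img))))
}

# TRUE at strict local maxima over the 8-neighbourhood (interior pixels).
local_maxima <- function(img) {
  ny <- nrow(img); nx <- ncol(img)
  if (ny < 3L || nx < 3L) return(matrix(FALSE, ny, nx))
  c0 <- img[2:(ny - 1), 2:(nx - 1)]
  res <- matrix(FALSE, ny, nx)
  ok <- c0 > img[1:(ny - 2), 2:(nx - 1)] & c0 > img[3:ny, 2:(nx - 1)] &
        c0 > img[2:(ny - 1), 1:(nx - 2)] & c0 > img[2:(ny - 1), 3:nx] &
        c0 > img[1:(ny - 2), 1:(nx - 2)] & c0 > img[1:(ny - 2), 3:nx] &
        c0 > img[3:ny, 1:(nx - 2)]      & c0 > img[3:ny, 3:nx]
  res[2:(ny - 1), 2:(nx - 1)] <- ok
  res
}

#' Fit a single diffraction-limited spot
#'
#' Least-squares fit of an isotropic 2D Gaussian plus constant background
#' over a square window centred on the initial position. The amplitude is
#' the fitted peak height above background; the integrated intensity is
#' `2 pi amplitude sigma^2`.
#'
#' @param image 2D numeric matrix `[y, x]`.
#' @param init_xy_nm numeric c(x, y) initial position in nm from the
#'   top-left pixel center.
#' @param pixel_size_nm pixel pitch in nm.
#' @param psf_fwhm_nm nominal PSF FWHM in nm (starting sigma).
#' @param sigma_bounds_nm allowed fitted sigma range in nm; default
#'   0.5-2 times the nominal PSF sigma.
#' @param window_sigmas half-width of the fit window in units of the maximum
#'   allowed sigma (default 3).
#' @return One-row data frame of class `spot_record`: `x_nm`, `y_nm`,
#'   `amplitude`, `sigma_nm`, `background`, `integrated`, `snr`, `rmse`,
#'   `converged`, `overlap`.
#' @export
fit_spot <- function(image, init_xy_nm, pixel_size_nm,
                     psf_fwhm_nm = 230,
                     sigma_bounds_nm = fwhm_to_sigma(psf_fwhm_nm) * c(0.5, 2),
                     window_sigmas = 3) {
  stopifnot(is.matrix(image))
  sigma0 <- fwhm_to_sigma(psf_fwhm_nm)
  half <- ceiling(window_sigmas * max(sigma_bounds_nm) / pixel_size_nm)
  if (nrow(image) < 2 * half + 1 || ncol(image) < 2 * half + 1)
    stop_invalid("image (%d x %d) smaller than the fit window (%d px)",
                 nrow(image), ncol(image), 2 * half + 1)
  cx <- round(init_xy_nm[1] / pixel_size_nm) + 1L
  cy <- round(init_xy_nm[2] / pixel_size_nm) + 1L
  if (cx < 1L || cx > ncol(image) || cy < 1L || cy > nrow(image))
    stop_invalid("initial position outside the image")
  cx <- min(max(cx, half + 1L), ncol(image) - half)
  cy <- min(max(cy, half + 1L), nrow(image) - half)
  rows <- (cy - half):(cy + half)
  cols <- (cx - half):(cx + half)
  win <- image[rows, cols]
  xg <- (cols - 1) * pixel_size_nm
  yg <- (rows - 1) * pixel_size_nm
  X <- matrix(rep(xg, each = length(yg)), nrow = length(yg))
  Y <- matrix(rep(yg, times = length(xg)), nrow = length(yg))

  b0 <- stats::median(c(win[1, ], win[nrow(win), ], win[, 1], win[, ncol(win)]))
  a0 <- max(win) - b0
  p0 <- c(x = init_xy_nm[1], y = init_xy_nm[2], a = a0, s = sigma0, b = b0)
  lower <- c(min(xg), min(yg), -Inf, sigma_bounds_nm[1], -Inf)
  upper <- c(max(xg), max(yg), Inf, sigma_bounds_nm[2], Inf)
  resid_fn <- function(p) {
    g <- p[3] * exp(-((X - p[1])^2 + (Y - p[2])^2) / (2 * p[4]^2)) + p[5]
    as.vector(g - win)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = p0, lower = lower, upper = upper, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  converged <- !is.null(fit) && fit$info %in% 1:4
  p <- if (is.null(fit)) p0 else fit$par
  rmse <- if (is.null(fit)) NA_real_ else sqrt(mean(fit$fvec^2))
  noise <- robust_sd(image - stats::median(image))
  structure(data.frame(
    x_nm = p[1], y_nm = p[2], amplitude = p[3], sigma_nm = p[4],
    background = p[5], integrated = 2 * pi * p[3] * p[4]^2,
    snr = if (noise > 0) abs(p[3]) / noise else Inf,
    rmse = rmse, converged = converged,
    overlap = is_overlapped(p[3], p[4], sigma0, rmse, noise)),
    class = c("spot_record", "data.frame"), row.names = 1L)
}

# Overlap heuristic: a single-Gaussian fit of two unresolved molecules shows
# an inflated width and/or residual structure clearly beyond the noise floor
# (only resolvable when the model mismatch exceeds the noise itself).
is_overlapped <- function(amplitude, sigma_fit, sigma_nominal, rmse, noise) {
  if (!is.finite(rmse) || amplitude <= 0) return(FALSE)
  mismatch <- if (noise > 1e-9 * abs(amplitude)) {
    rmse > 1.5 * noise
  } else {
    rmse > 0.005 * abs(amplitude)
  }
  (sigma_fit > 1.15 * sigma_nominal) || mismatch
}

#' Detect diffraction-limited spots in one image
#'
#' Difference-of-Gaussians band-pass, strict local maxima above
#' `min_snr` times the robust (MAD) noise of the band-passed image, each
#' refined by [fit_spot()]. Candidates converging to within half a PSF FWHM
#' of a stronger detection are merged into it; merged or poorly modelled
#' detections carry an overlap flag.
#'
#' @param image 2D numeric matrix `[y, x]`.
#' @param pixel_size_nm pixel pitch in nm.
#' @param psf_fwhm_nm expected spot FWHM in nm.
#' @param min_snr detection threshold in units of robust background sd.
#' @param sigma_bounds_nm acceptable fitted sigma range in nm.
#' @return data frame of class `spot_record` (possibly 0 rows), one row per
#'   detection, sorted by decreasing amplitude.
#' @export
detect_spots <- function(image, pixel_size_nm, psf_fwhm_nm = 230,
                         min_snr = 5,
                         sigma_bounds_nm = fwhm_to_sigma(psf_fwhm_nm) * c(0.5, 2)) {
  stopifnot(is.matrix(image))
  check_number(min_snr, "min_snr", 0, strict_lower = TRUE)
  sigma_px <- fwhm_to_sigma(psf_fwhm_nm) / pixel_size_nm
  dog <- gaussian_blur(image, sigma_px / sqrt(2)) -
         gaussian_blur(image, sigma_px * sqrt(2))
  thr <- min_snr * robust_sd(dog)
  cand <- which(local_maxima(dog) & dog > thr, arr.ind = TRUE)
  if (!nrow(cand)) return(empty_spot_table())
  ord <- order(dog[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]

  noise <- robust_sd(image - stats::median(image))
  recs <- list()
  for (i in seq_len(nrow(cand))) {
    init <- c((cand[i, 2] - 1) * pixel_size_nm,
              (cand[i, 1] - 1) * pixel_size_nm)
    rec <- tryCatch(
      fit_spot(image, init, pixel_size_nm, psf_fwhm_nm, sigma_bounds_nm),
      error = function(e) NULL)
    if (is.null(rec) || !rec$converged) next
    if (rec$amplitude < min_snr * noise) next
    if (rec$sigma_nm <= sigma_bounds_nm[1] * 1.001 ||
        rec$sigma_nm >= sigma_bounds_nm[2] * 0.999) next
    dup <- FALSE
    for (j in seq_along(recs)) {
      d <- sqrt((recs[[j]]$x_nm - rec$x_nm)^2 + (recs[[j]]$y_nm - rec$y_nm)^2)
      if (d < psf_fwhm_nm) {  # same molecule (or unresolved pair): keep stronger
        dup <- TRUE
        if (rec$amplitude > recs[[j]]$amplitude) {
          rec$overlap <- rec$overlap || d > 0.5 * psf_fwhm_nm
          recs[[j]] <- rec
        } else {
          recs[[j]]$overlap <- recs[[j]]$overlap || d > 0.5 * psf_fwhm_nm
        }
        break
      }
    }
    if (!dup) recs[[length(recs) + 1L]] <- rec
  }
  if (!length(recs)) return(empty_spot_table())
  out <- do.call(rbind, recs)
  out <- out[order(-out$amplitude), ]
  rownames(out) <- NULL
  class(out) <- c("spot_record", "data.frame")
  out
}

empty_spot_table <- function() {
  structure(data.frame(x_nm = numeric(), y_nm = numeric(),
                       amplitude = numeric(), sigma_nm = numeric(),
                       background = numeric(), integrated = numeric(),
                       snr = numeric(), rmse = numeric(),
                       converged = logical(), overlap = logical()),
            class = c("spot_record", "data.frame"))
}

# Linear amplitude + background estimate with the spot shape locked
# (known centroid and sigma): closed-form least squares.
locked_amplitude <- function(image, x_nm, y_nm, sigma_nm, pixel_size_nm,
                             window_sigmas = 3) {
  half <- ceiling(window_sigmas * sigma_nm / pixel_size_nm)
  cx <- round(x_nm / pixel_size_nm) + 1L
  cy <- round(y_nm / pixel_size_nm) + 1L
  if (cx - half < 1L || cx + half > ncol(image) ||
      cy - half < 1L || cy + half > nrow(image))
    stop_invalid("spot at (%.0f, %.0f) nm too close to the border", x_nm, y_nm)
  rows <- (cy - half):(cy + half)
  cols <- (cx - half):(cx + half)
  win <- image[rows, cols]
  xg <- (cols - 1) * pixel_size_nm
  yg <- (rows - 1) * pixel_size_nm
  g <- exp(-(outer((yg - y_nm)^2, (xg - x_nm)^2, `+`)) / (2 * sigma_nm^2))
  A <- cbind(as.vector(g), 1)
  coef <- stats::.lm.fit(A, as.vector(win))$coefficients
  c(amplitude = coef[1], background = coef[2])
}

#' Extract a per-spot spectrum from a hyperspectral stack
#'
#' With the centroid and width locked to the detected spot (immobilized
#' molecules do not move between bands), the amplitude and local background
#' at each band reduce to a linear least-squares problem. Returns the
#' background-corrected amplitude per wavenumber.
#'
#' @param stack a [hyperspectral_stack()].
#' @param spot a `spot_record` row (from [detect_spots()] or [fit_spot()]).
#' @return data frame of class `spot_spectrum`: `wavenumber_cm1`,
#'   `intensity`, plus attribute `background_corrected = TRUE`.
#' @export
extract_spectrum <- function(stack, spot) {
  stopifnot(inherits(stack, "hyperspectral_stack"))
  spot <- as.data.frame(spot)[1, ]
  nb <- n_pages(stack)
  amp <- numeric(nb)
  for (b in seq_len(nb)) {
    a <- locked_amplitude(stack$data[, , b], spot$x_nm, spot$y_nm,
                          spot$sigma_nm, stack$pixel_size_nm)
    amp[b] <- a["amplitude"]
  }
  structure(data.frame(wavenumber_cm1 = stack$wavenumber, intensity = amp),
            background_corrected = TRUE,
            class = c("spot_spectrum", "data.frame"))
}

#' Track a spot's intensity through a time-lapse stack
#'
#' Locked-position amplitude fit per frame (the molecule is immobilized);
#' returns the per-frame background-corrected amplitude as an intensity
#' trace.
#'
#' @param stack a [time_lapse_stack()].
#' @param position_nm numeric c(x, y) in nm.
#' @param sigma_nm spot sigma in nm; default the 230 nm PSF.
#' @return An [intensity_trace()].
#' @export
track_spot_trace <- function(stack, position_nm,
                             sigma_nm = fwhm_to_sigma(230)) {
  stopifnot(inherits(stack, "time_lapse_stack"))
  nf <- n_pages(stack)
  amp <- numeric(nf)
  for (f in seq_len(nf)) {
    a <- locked_amplitude(stack$data[, , f], position_nm[1], position_nm[2],
                          sigma_nm, stack$pixel_size_nm)
    amp[f] <- a["amplitude"]
  }
  intensity_trace((seq_len(nf) - 1L) * stack$dt, amp)
}

#' Denoising hook
#'
#' Interface point for plugging in learned denoisers; ships with a running
#' frame-average baseline which reduces independent noise by `sqrt(n)`.
#'
#' @param stack a [hyperspectral_stack()] or [time_lapse_stack()].
#' @param method `"none"` (identity) or `"frame_average"`.
#' @param n window length for `frame_average` (>= 1; centred running mean
#'   with shrinking windows at the ends, output shape unchanged).
#' @return A stack of the same class and shape.
#' @export
denoise_hook <- function(stack, method = c("none", "frame_average"), n = 1L) {
  if (!is.character(method) || !all(method %in% c("none", "frame_average")))
    stop_invalid("unknown denoise method '%s'", paste(method[1]))
  method <- match.arg(method)
  if (method == "none") return(stack)
  n <- as.integer(n)
  if (n < 1L) stop_invalid("frame_average needs n >= 1")
  if (n == 1L) return(stack)
  np <- n_pages(stack)
  half_lo <- (n - 1L) %/% 2L
  half_hi <- n - 1L - half_lo
  out <- stack$data
  for (p in seq_len(np)) {
    sel <- max(1L, p - half_lo):min(np, p + half_hi)
    out[, , p] <- apply(stack$data[, , sel, drop = FALSE], c(1, 2), mean)
  }
  stack$data <- out
  stack
}
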