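#' Reference spectral library
#'
#' Named reference spectra on a common wavenumber grid, normalized to unit
#' maximum, for pixel-wise unmixing.
#'
#' @param wavenumber common grid in cm^-1.
#' @param spectra numeric matrix (bands x references) or a named list of
#'   vectors.
#' @param names reference names (defaults to column/list names).
#' @return An object of class `reference_library`.
#' @export
reference_library <- function(wavenumber, spectra, names = NULL) {
  if (is.list(spectra) && !is.data.frame(spectra))
    spectra <- do.call(cbind, spectra)
  spectra <- as.matrix(spectra)
  if (nrow(spectra) != length(wavenumber))
    stop_invalid("spectra rows (%d) != axis length (%d)",
                 nrow(spectra), length(wavenumber))
  if (is.null(names)) names <- colnames(spectra)
  if (is.null(names)) names <- paste0("ref", seq_len(ncol(spectra)))
  mx <- apply(abs(spectra), 2, max)
  if (any(mx == 0)) stop_invalid("all-zero reference spectrum")
  spectra <- sweep(spectra, 2, mx, "/")
  colnames(spectra) <- names
  structure(list(wavenumber = as.numeric(wavenumber), spectra = spectra),
            class = "reference_library")
}

# (Non-negative) LASSO by cyclic coordinate descent: minimize
# ||y - R c||^2 + lambda * sum(penalty_j |c_j|), with c_j >= 0 where
# `nonneg` (recycled per column) is TRUE. Penalty weight 0 exempts a column
# (used for baseline columns in band fitting).
lasso_cd <- function(R, y, lambda, nonneg = TRUE, tol = 1e-12,
                     max_iter = 10000L, penalty = 1) {
  p <- ncol(R)
  nonneg <- rep_len(nonneg, p)
  penalty <- rep_len(penalty, p)
  rr <- colSums(R^2)
  c_hat <- rep(0, p)
  resid <- y
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(p)) {
      rho <- sum(R[, j] * resid) + rr[j] * c_hat[j]
      lam <- lambda * penalty[j]
      new <- if (nonneg[j]) {
        max(0, (rho - lam / 2) / rr[j])
      } else {
        sign(rho) * max(0, (abs(rho) - lam / 2)) / rr[j]
      }
      if (new != c_hat[j]) {
        resid <- resid - R[, j] * (new - c_hat[j])
        delta <- max(delta, abs(new - c_hat[j]))
      }
      c_hat[j] <- new
    }
    if (delta < tol * (1 + max(abs(c_hat)))) break
  }
  c_hat
}

#' LASSO spectral unmixing
#'
#' Per pixel (or for a single spectrum), finds non-negative coefficients
#' minimizing `||spectrum - sum_i coef_i ref_i||^2 + lambda * sum_i |coef_i|`
#' by cyclic coordinate descent. At `lambda = 0` this reduces to
#' non-negative least squares.
#'
#' @param x a [hyperspectral_stack()], a numeric matrix (pixels x bands), or
#'   a single spectrum vector on the library grid.
#' @param library a [reference_library()] on the same wavenumber grid.
#' @param lambda L1 regularization weight (>= 0).
#' @param nonneg constrain coefficients to be non-negative (default TRUE;
#'   abundances are physical concentrations).
#' @param tol,max_iter coordinate-descent stopping rule.
#' @param wavenumber required when `x` is a bare vector/matrix, to check
#'   grid alignment.
#' @return For a stack: an object of class `abundance_map` (array
#'   `[ny, nx, n_refs]` plus metadata). Otherwise a named coefficient vector
#'   (or matrix, one row per pixel).
#' @export
lasso_unmix <- function(x, library, lambda = 0, nonneg = TRUE,
                        tol = 1e-12, max_iter = 10000L, wavenumber = NULL) {
  stopifnot(inherits(library, "reference_library"))
  check_number(lambda, "lambda", 0)
  R <- library$spectra
  if (qr(R)$rank < ncol(R))
    warning("reference spectra are collinear; coefficients may not be unique")
  check_grid <- function(wn) {
    if (length(wn) != length(library$wavenumber) ||
        any(abs(wn - library$wavenumber) > 1e-6))
      stop_invalid("spectrum grid does not match the library grid")
  }
  if (inherits(x, "hyperspectral_stack")) {
    check_grid(x$wavenumber)
    d <- dim(x$data)
    px <- matrix(x$data, d[1] * d[2], d[3])
    coefs <- t(apply(px, 1L, function(y)
      lasso_cd(R, y, lambda, nonneg, tol, max_iter)))
    arr <- array(coefs, dim = c(d[1], d[2], ncol(R)),
                 dimnames = list(NULL, NULL, colnames(R)))
    return(structure(list(abundance = arr, lambda = lambda, nonneg = nonneg,
                          references = colnames(R),
                          pixel_size_nm = x$pixel_size_nm),
                     class = "abundance_map"))
  }
  if (is.null(dim(x))) {
    if (!is.null(wavenumber)) check_grid(wavenumber)
    if (length(x) != nrow(R))
      stop_invalid("spectrum length (%d) != library grid (%d)",
                   length(x), nrow(R))
    co <- lasso_cd(R, as.numeric(x), lambda, nonneg, tol, max_iter)
    return(stats::setNames(co, colnames(R)))
  }
  x <- as.matrix(x)
  if (!is.null(wavenumber)) check_grid(wavenumber)
  if (ncol(x) != nrow(R))
    stop_invalid("spectra columns (%d) != library grid (%d)", ncol(x), nrow(R))
  out <- t(apply(x, 1L, function(y) lasso_cd(R, y, lambda, nonneg, tol,
                                             max_iter)))
  colnames(out) <- colnames(R)
  out
}

#' Cross-validated choice of the unmixing regularization weight
#'
#' K-fold cross-validation over spectral bands: for each candidate lambda,
#' coefficients are fitted on the training bands and scored by squared
#' prediction error on the held-out bands.
#'
#' @param x spectrum vector (or matrix, pixels x bands; errors are summed
#'   over pixels).
#' @param library a [reference_library()].
#' @param lambdas candidate weights (>= 0).
#' @param folds number of folds (default 5).
#' @param seed fold-assignment seed.
#' @inheritParams lasso_unmix
#' @return data frame (`lambda`, `cv_error`) with attribute `best` (the
#'   lambda with minimum CV error).
#' @export
select_lambda <- function(x, library, lambdas = 10^seq(-4, 1, length.out = 12),
                          folds = 5L, seed = 1L, nonneg = TRUE) {
  stopifnot(inherits(library, "reference_library"))
  X <- if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
  R <- library$spectra
  if (ncol(X) != nrow(R))
    stop_invalid("spectra columns (%d) != library grid (%d)", ncol(X), nrow(R))
  fold_id <- withr::with_seed(as.integer(seed),
                              sample(rep_len(seq_len(folds), nrow(R))))
  errs <- vapply(lambdas, function(l) {
    tot <- 0
    for (f in seq_len(folds)) {
      hold <- fold_id == f
      for (i in seq_len(nrow(X))) {
        co <- lasso_cd(R[!hold, , drop = FALSE], X[i, !hold], l, nonneg)
        tot <- tot + sum((X[i, hold] - R[hold, , drop = FALSE] %*% co)^2)
      }
    }
    tot
  }, 0)
  out <- data.frame(lambda = lambdas, cv_error = errs)
  attr(out, "best") <- lambdas[which.min(errs)]
  out
}

#' @export
print.abundance_map <- function(x, ...) {
  d <- dim(x$abundance)
  cat(sprintf("<abundance_map> %d x %d px, references: %s (lambda = %g%s)\n",
              d[2], d[1], paste(x$references, collapse = ", "), x$lambda,
              if (x$nonneg) ", non-negative" else ""))
  invisible(x)
}

#' Four-band amide-I deconvolution
#'
#' Decomposes an amide-I spectrum into four pseudo-Voigt bands -- aromatic
#' ring modes (~1615 cm^-1), alpha-helix (~1656), beta-sheet (~1671) and
#' extended structures (~1680). Structural fractions are each structural
#' band's area over the summed alpha + beta + extended area (the ring band,
#' not being secondary structure, is excluded from the denominator).
#'
#' Because the three structural components overlap heavily, their areas are
#' only statistically identifiable when the line shapes are constrained. The
#' default estimator therefore treats the component widths and mixing as
#' known reference values (the same band library the synthetic generator
#' uses), and solves the band amplitudes and a linear baseline by non-negative
#' linear least squares. Band centers can additionally be refined within
#' the constraint window (`refine = "centers"`, variable projection). The
#' unconstrained fit with free widths (`width_bounds`) and per-band mixing
#' is available as `refine = "full"`; it is appropriate only at high
#' signal-to-noise.
#'
#' @param wavenumber grid in cm^-1; must cover all four constraint windows.
#' @param intensity spectrum values.
#' @param centers nominal band centers (cm^-1), named
#'   ring/alpha/beta/extended.
#' @param widths reference FWHMs in cm^-1 (same order as `centers`).
#' @param eta reference Lorentzian mixing fraction.
#' @param center_window allowed deviation from the nominal centers (cm^-1).
#' @param refine `"none"` (default: all line shapes from the reference
#'   library, amplitudes and baseline linear), `"centers"` (additionally
#'   refine band centers in the window), or `"full"`.
#' @param width_bounds FWHM bounds in cm^-1, used by `refine = "full"`.
#' @return An object of class `amide_fit`: `bands` (label, center, fwhm,
#'   eta, height, area), `fractions` (percent alpha/beta/extended, summing
#'   to 100), `converged`, `fitted`, `baseline`, and the input spectrum.
#' @export
deconvolve_amide <- function(wavenumber, intensity,
                             centers = AMIDE_CENTERS, widths = AMIDE_WIDTHS,
                             eta = 0.5, center_window = 5,
                             refine = c("none", "centers", "full"),
                             width_bounds = c(8, 40)) {
  refine <- match.arg(refine)
  wavenumber <- as.numeric(wavenumber); intensity <- as.numeric(intensity)
  if (length(wavenumber) != length(intensity))
    stop_invalid("axis and intensity lengths differ")
  if (min(wavenumber) > min(centers) - center_window ||
      max(wavenumber) < max(centers) + center_window)
    stop_invalid("spectrum must cover all four constraint windows")
  nb <- length(centers)
  y <- intensity
  wc <- (wavenumber - mean(wavenumber)) / diff(range(wavenumber))

  # linear sub-problem: non-negative band amplitudes + free linear baseline
  basis <- function(cs, ws, es) {
    cbind(vapply(seq_len(nb), function(i)
      pseudo_voigt(wavenumber, cs[i], ws[i], es[i]),
      numeric(length(wavenumber))), 1, wc)
  }
  solve_lin <- function(B) lasso_cd(B, y, lambda = 0,
                                    nonneg = c(rep(TRUE, nb), FALSE, FALSE))

  es <- rep_len(eta, nb)
  ws <- widths
  cs <- centers
  converged <- TRUE
  if (refine == "centers") {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = cs, lower = centers - center_window,
                         upper = centers + center_window,
                         fn = function(cc) {
                           B <- basis(cc, ws, es)
                           as.vector(B %*% solve_lin(B) - y)
                         },
                         control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (!is.null(fit)) cs <- fit$par
    converged <- !is.null(fit) && fit$info %in% 1:4
    B <- basis(cs, ws, es)
    co <- solve_lin(B)
    hs <- co[seq_len(nb)]
    base_co <- co[nb + 1:2]
  } else if (refine == "none") {
    B <- basis(cs, ws, es)
    co <- solve_lin(B)
    hs <- co[seq_len(nb)]
    base_co <- co[nb + 1:2]
  } else {  # full nonlinear fit: centers, widths, heights, mixing, baseline
    B <- basis(cs, ws, es)
    co <- solve_lin(B)
    p0 <- c(cs, ws, co[seq_len(nb)], es, co[nb + 1:2])
    lower <- c(centers - center_window, rep(width_bounds[1], nb),
               rep(0, nb), rep(0, nb), -Inf, -Inf)
    upper <- c(centers + center_window, rep(width_bounds[2], nb),
               rep(Inf, nb), rep(1, nb), Inf, Inf)
    model <- function(p) {
      rowSums(vapply(seq_len(nb), function(i)
        p[2 * nb + i] * pseudo_voigt(wavenumber, p[i], p[nb + i],
                                     p[3 * nb + i]),
        numeric(length(wavenumber)))) + p[4 * nb + 1] + p[4 * nb + 2] * wc
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                         fn = function(p) model(p) - y,
                         control = minpack.lm::nls.lm.control(maxiter = 1000,
                                                              maxfev = 50000)),
      error = function(e) NULL)
    converged <- !is.null(fit) && fit$info %in% 1:4
    p <- if (is.null(fit)) p0 else fit$par
    cs <- p[1:nb]; ws <- p[nb + 1:nb]; hs <- p[2 * nb + 1:nb]
    es <- p[3 * nb + 1:nb]; base_co <- p[4 * nb + 1:2]
  }

  areas <- hs * pseudo_voigt_area(ws, es)
  labels <- names(centers)
  if (is.null(labels)) labels <- c("ring", "alpha", "beta", "extended")[seq_len(nb)]
  structural <- labels != "ring"
  tot <- sum(areas[structural])
  if (tot <= 0) stop_invalid("no structural band area found")
  fractions <- 100 * areas[structural] / tot
  names(fractions) <- labels[structural]
  base_vals <- base_co[1] + base_co[2] * wc
  comp <- rowSums(vapply(seq_len(nb), function(i)
    hs[i] * pseudo_voigt(wavenumber, cs[i], ws[i], es[i]),
    numeric(length(wavenumber))))
  structure(list(bands = data.frame(label = labels, center = unname(cs),
                                    fwhm = unname(ws), eta = unname(es),
                                    height = unname(hs),
                                    area = unname(areas)),
                 fractions = fractions, converged = converged,
                 refine = refine,
                 wavenumber = wavenumber, intensity = intensity,
                 baseline = base_vals, fitted = comp + base_vals),
            class = "amide_fit")
}

#' @export
print.amide_fit <- function(x, ...) {
  cat(sprintf("<amide_fit>%s\n", if (x$converged) "" else "  [NOT converged]"))
  print(x$bands, digits = 4)
  cat(sprintf("  structural fractions: alpha %.1f%%, beta %.1f%%, extended %.1f%%\n",
              x$fractions["alpha"], x$fractions["beta"],
              x$fractions["extended"]))
  invisible(x)
}

#' @export
coef.amide_fit <- function(object, ...) object$fractions

#' @export
residuals.amide_fit <- function(object, ...) object$intensity - object$fitted

#' Regenerate the fitted amide spectrum
#' @param object an [deconvolve_amide()] result.
#' @param wavenumber optional new grid (defaults to the fit grid).
#' @param ... unused.
#' @return fitted intensities (baseline excluded).
#' @export
predict.amide_fit <- function(object, wavenumber = object$wavenumber, ...) {
  b <- object$bands
  rowSums(vapply(seq_len(nrow(b)), function(i)
    b$height[i] * pseudo_voigt(wavenumber, b$center[i], b$fwhm[i], b$eta[i]),
    numeric(length(wavenumber))))
}

#' @export
plot.amide_fit <- function(x, ...) {
  graphics::plot(x$wavenumber, x$intensity, type = "l",
                 xlab = expression(wavenumber ~ (cm^-1)),
                 ylab = "intensity", ...)
  graphics::lines(x$wavenumber, x$fitted, col = "red3")
  b <- x$bands
  cols <- c(ring = "blue3", alpha = "green4", beta = "orange3",
            extended = "red")
  for (i in seq_len(nrow(b)))
    graphics::lines(x$wavenumber,
                    x$baseline + b$height[i] *
                      pseudo_voigt(x$wavenumber, b$center[i], b$fwhm[i],
                                   b$eta[i]),
                    col = cols[b$label[i]], lty = 2)
  invisible(x)
}

#' Classify the C-H stretching band
#'
#' Locates the dominant peak in the 2800-3100 cm^-1 window by parabolic
#' interpolation around the maximum sample and labels the spectrum
#' "immunoglobulin-like" (CH3 stretch near 2939 cm^-1) or
#' "non-immunoglobulin" (near 2930 cm^-1), the midpoint 2934.5 cm^-1 being
#' the boundary.
#'
#' @param wavenumber grid in cm^-1.
#' @param intensity spectrum values.
#' @param window search window c(lo, hi) in cm^-1.
#' @return list with `center_cm1` and `label`.
#' @export
classify_ch_band <- function(wavenumber, intensity,
                             window = c(2800, 3100)) {
  sel <- which(wavenumber >= window[1] & wavenumber <= window[2])
  if (length(sel) < 3L) stop_invalid("too few samples in the C-H window")
  w <- wavenumber[sel]; y <- intensity[sel]
  i <- which.max(y)
  rng <- diff(range(y))
  if (rng <= 0 || (y[i] - stats::median(y)) < 1e-6 * max(abs(y), 1))
    stop_invalid("no peak found in the C-H window")
  if (i == 1L || i == length(y)) {
    center <- w[i]
  } else {
    # parabola through the three samples around the maximum
    dy1 <- y[i - 1]; dy2 <- y[i]; dy3 <- y[i + 1]
    denom <- dy1 - 2 * dy2 + dy3
    shift <- if (denom != 0) 0.5 * (dy1 - dy3) / denom else 0
    step <- (w[i + 1] - w[i - 1]) / 2
    center <- w[i] + shift * step
  }
  label <- if (abs(center - 2939) < abs(center - 2930))
    "immunoglobulin-like" else "non-immunoglobulin"
  list(center_cm1 = center, label = label)
}

#' Background-corrected band intensity ratio
#'
#' Ratio of intensities at two wavenumbers after subtracting a linear
#' baseline through the spectrum's end points; used e.g. for the
#' 2880/2939 cm^-1 denaturation marker and the 2959/2930 cm^-1 DNA-content
#' readout of viral capsids.
#'
#' @param wavenumber grid in cm^-1.
#' @param intensity spectrum values.
#' @param nu1,nu2 numerator and denominator wavenumbers (must lie within
#'   half a grid step of a sample).
#' @param baseline subtract the end-point linear baseline first (default
#'   TRUE).
#' @return `intensity(nu1) / intensity(nu2)`.
#' @export
band_ratio <- function(wavenumber, intensity, nu1, nu2, baseline = TRUE) {
  i1 <- grid_index(wavenumber, nu1)
  i2 <- grid_index(wavenumber, nu2)
  y <- intensity
  if (baseline) {
    n <- length(wavenumber)
    slope <- (intensity[n] - intensity[1]) / (wavenumber[n] - wavenumber[1])
    y <- intensity - (intensity[1] + slope * (wavenumber - wavenumber[1]))
  }
  if (y[i2] <= 0)
    stop_invalid("denominator intensity at %g cm^-1 is not positive", nu2)
  y[i1] / y[i2]
}
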