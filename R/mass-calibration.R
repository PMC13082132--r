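#' Gaussian mixture fit of per-spot intensities
#'
#' Maximum-likelihood Gaussian mixture on the raw intensity values (bin-free,
#' not a fit of histogram counts), solved by expectation-maximization with
#' k-means initialization from the given seed. Components are reported
#' sorted by mean. Intensity histograms of single molecules show quantized,
#' integer-multiple peaks (monomer/dimer/trimer), which this fit resolves.
#'
#' @param values numeric vector of intensities (at least `10 * k` values).
#' @param k number of components (>= 1).
#' @param seed integer seed for the k-means initialization.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @return An object of class `mixture_fit`: `means`, `sds`, `weights`
#'   (sorted by mean), `loglik`, `bic`, `converged`, `k`, `n`, `seed`.
#' @seealso [select_components()] for a BIC scan over k.
#' @export
fit_mixture <- function(values, k, seed = 1L, max_iter = 500, tol = 1e-8) {
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  k <- as.integer(k)
  if (k < 1L) stop_invalid("k must be >= 1")
  n <- length(values)
  if (n < 10L * k)
    stop_invalid("need at least %d values for k = %d (got %d)", 10L * k, k, n)
  scale <- stats::sd(values)
  if (!is.finite(scale) || scale < 1e-12 * max(abs(values), 1))
    stop_invalid("degenerate sample: values have (near-)zero variance")

  if (k == 1L) {
    mu <- mean(values); sd1 <- stats::sd(values) * sqrt((n - 1) / n)
    ll <- sum(stats::dnorm(values, mu, sd1, log = TRUE))
    return(new_mixture_fit(mu, sd1, 1, ll, TRUE, k, n, seed))
  }

  km <- withr::with_seed(as.integer(seed),
                         stats::kmeans(values, centers = k, nstart = 10))
  mu <- as.numeric(km$centers)
  sds <- vapply(seq_len(k), function(j) {
    v <- values[km$cluster == j]
    s <- if (length(v) > 1L) stats::sd(v) else scale / 10
    max(s, scale * 1e-3)
  }, 0)
  w <- as.numeric(table(factor(km$cluster, levels = seq_len(k)))) / n

  ll_old <- -Inf; converged <- FALSE
  for (it in seq_len(max_iter)) {
    logd <- vapply(seq_len(k), function(j)
      log(w[j]) + stats::dnorm(values, mu[j], sds[j], log = TRUE),
      numeric(n))
    m <- apply(logd, 1L, max)
    lse <- m + log(rowSums(exp(logd - m)))
    ll <- sum(lse)
    r <- exp(logd - lse)
    nk <- colSums(r)
    if (any(nk < 1e-8)) break  # component collapsed
    w <- nk / n
    mu <- colSums(r * values) / nk
    sds <- sqrt(colSums(r * (outer(values, mu, `-`))^2) / nk)
    if (any(sds < scale * 1e-6)) break  # degenerate variance
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + 1)) {
      converged <- TRUE; ll_old <- ll; break
    }
    ll_old <- ll
  }
  ord <- order(mu)
  new_mixture_fit(mu[ord], sds[ord], w[ord], ll_old, converged, k, n, seed)
}

new_mixture_fit <- function(means, sds, weights, loglik, converged, k, n, seed) {
  p <- 3L * k - 1L
  structure(list(means = means, sds = sds, weights = weights,
                 loglik = loglik, bic = -2 * loglik + p * log(n),
                 converged = converged, k = k, n = n,
                 seed = as.integer(seed)),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> k = %d, n = %d, logLik = %.2f, BIC = %.2f%s\n",
              x$k, x$n, x$loglik, x$bic,
              if (x$converged) "" else "  [NOT converged]"))
  tab <- data.frame(mean = x$means, sd = x$sds, weight = x$weights)
  dim_flag <- dimer_components(x)
  if (any(dim_flag)) tab$note <- ifelse(dim_flag, "dimer/coincidence", "")
  print(tab, digits = 4)
  invisible(x)
}

#' @export
coef.mixture_fit <- function(object, ...) {
  data.frame(mean = object$means, sd = object$sds, weight = object$weights)
}

#' Flag dimer / coincidence components
#'
#' Secondary components whose mean lies near twice the dominant (highest
#' weight) component's mean arise from protein dimers or from two molecules
#' closer than the diffraction limit; they are reported but should be
#' excluded from calibration means.
#'
#' @param fit a [fit_mixture()] result.
#' @param tol relative tolerance around 2x the dominant mean.
#' @return logical vector, one entry per component.
#' @export
dimer_components <- function(fit, tol = 0.15) {
  main <- fit$means[which.max(fit$weights)]
  is_dimer <- abs(fit$means / (2 * main) - 1) < tol
  is_dimer & seq_along(fit$means) != which.max(fit$weights)
}

#' Scan the number of mixture components by BIC
#'
#' @param values numeric intensities.
#' @param k_max largest k to try (>= 1).
#' @param seed seed forwarded to each [fit_mixture()].
#' @return data frame (`k`, `bic`, `converged`) with attribute `best`
#'   (the k minimizing BIC among converged fits).
#' @export
select_components <- function(values, k_max = 5, seed = 1L) {
  ks <- seq_len(k_max)
  fits <- lapply(ks, function(k)
    tryCatch(fit_mixture(values, k, seed), error = function(e) NULL))
  out <- data.frame(
    k = ks,
    bic = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$bic, 0),
    converged = vapply(fits, function(f) !is.null(f) && f$converged, NA))
  ok <- which(out$converged)
  attr(out, "best") <- if (length(ok)) out$k[ok[which.min(out$bic[ok])]] else NA_integer_
  out
}

#' Linear intensity-mass calibration
#'
#' Ordinary least-squares fit of component mean intensity against sequence
#' mass (free intercept). Residuals are re-expressed in kDa through the
#' fitted slope; `average_error_pct` is the mean relative deviation between
#' measured and sequence mass, and `mass_accuracy_kda` the largest absolute
#' deviation.
#'
#' @param intensity mean intensity per calibrant (detector units).
#' @param mass_kda calibrant sequence masses in kDa (distinct, >= 2 points).
#' @return An object of class `mass_calibration`: `slope`, `intercept`,
#'   `calibrants` (per-point table with kDa and percent residuals),
#'   `average_error_pct`, `mass_accuracy_kda`, and the underlying `lm` fit.
#' @export
fit_calibration <- function(intensity, mass_kda) {
  if (length(intensity) != length(mass_kda))
    stop_invalid("intensity and mass lengths differ")
  if (length(mass_kda) < 2L) stop_invalid("need at least 2 calibrants")
  if (anyDuplicated(mass_kda)) stop_invalid("calibrant masses must be distinct")
  fit <- stats::lm(intensity ~ mass_kda)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) || slope <= 0)
    warning("calibration slope is not positive; mass estimates are invalid")
  mass_hat <- (intensity - intercept) / slope
  resid_kda <- mass_hat - mass_kda
  resid_pct <- 100 * abs(resid_kda) / mass_kda
  structure(list(slope = slope, intercept = intercept,
                 calibrants = data.frame(mass_kda = mass_kda,
                                         intensity = intensity,
                                         measured_kda = mass_hat,
                                         residual_kda = resid_kda,
                                         residual_pct = resid_pct),
                 average_error_pct = mean(resid_pct),
                 mass_accuracy_kda = max(abs(resid_kda)),
                 lm = fit),
            class = "mass_calibration")
}

#' @export
print.mass_calibration <- function(x, ...) {
  cat(sprintf("<mass_calibration> intensity = %.4g + %.4g * mass[kDa]\n",
              x$intercept, x$slope))
  cat(sprintf("  average error: %.2f%%   mass accuracy: %.2f kDa   (n = %d)\n",
              x$average_error_pct, x$mass_accuracy_kda, nrow(x$calibrants)))
  invisible(x)
}

#' @export
summary.mass_calibration <- function(object, ...) {
  print(object)
  print(object$calibrants, digits = 4)
  invisible(object)
}

#' @export
coef.mass_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
residuals.mass_calibration <- function(object, ...) {
  object$calibrants$residual_kda
}

#' Predicted intensity at given masses
#' @param object a [fit_calibration()] result.
#' @param mass_kda masses in kDa.
#' @param ... unused.
#' @return predicted intensities.
#' @export
predict.mass_calibration <- function(object, mass_kda, ...) {
  object$intercept + object$slope * mass_kda
}

#' @export
plot.mass_calibration <- function(x, ...) {
  cal <- x$calibrants
  graphics::plot(cal$mass_kda, cal$intensity, pch = 19,
                 xlab = "mass (kDa)", ylab = "intensity (detector units)", ...)
  graphics::abline(x$intercept, x$slope, col = "red3")
  invisible(x)
}

#' Invert the calibration: intensity to mass
#'
#' `mass = (intensity - intercept) / slope`. Non-positive results are
#' returned with a warning (flagged estimates).
#'
#' @param intensity intensities in detector units (vectorized).
#' @param calibration a [fit_calibration()] result with positive slope.
#' @return masses in kDa.
#' @export
estimate_mass <- function(intensity, calibration) {
  stopifnot(inherits(calibration, "mass_calibration"))
  if (!is.finite(calibration$slope) || calibration$slope <= 0)
    stop_invalid("calibration slope must be positive")
  m <- (intensity - calibration$intercept) / calibration$slope
  if (any(m <= 0))
    warning(sprintf("%d non-positive mass estimate(s); flagged as invalid",
                    sum(m <= 0)))
  m
}

#' Power-law fit of intensity versus particle diameter
#'
#' Least-squares slope of `log(intensity)` on `log(diameter)`; the
#' interference-dominated signal follows d^3 while pure scattering follows
#' d^6.
#'
#' @param diameter_nm particle diameters in nm (> 0, >= 2 distinct sizes).
#' @param intensity corresponding intensities (> 0).
#' @return An object of class `power_law_fit`: `exponent`, `prefactor`,
#'   `r_squared`.
#' @export
fit_power_law <- function(diameter_nm, intensity) {
  if (length(diameter_nm) != length(intensity))
    stop_invalid("diameter and intensity lengths differ")
  if (length(diameter_nm) < 2L) stop_invalid("need at least 2 sizes")
  if (any(diameter_nm <= 0) || any(intensity <= 0))
    stop_invalid("power-law fit requires positive values on both axes")
  fit <- stats::lm(log(intensity) ~ log(diameter_nm))
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits are expected
  structure(list(exponent = unname(stats::coef(fit)[2]),
                 prefactor = exp(unname(stats::coef(fit)[1])),
                 r_squared = r2),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> intensity = %.4g * d^%.4f  (R^2 = %.5f)\n",
              x$prefactor, x$exponent, x$r_squared))
  invisible(x)
}

#' @export
coef.power_law_fit <- function(object, ...) {
  c(prefactor = object$prefactor, exponent = object$exponent)
}
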