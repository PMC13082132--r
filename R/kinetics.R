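#' Two-state idealization of an intensity trace
#'
#' Threshold crossing with hysteresis: a frame is bound when the intensity
#' exceeds `threshold + hysteresis/2`, unbound below
#' `threshold - hysteresis/2`, and keeps the previous state in between. With
#' `threshold = NULL` the threshold is placed at the midpoint of the two
#' means of a 2-component Gaussian mixture of the trace values; if the two
#' components are not separated (unimodal trace) this auto-thresholding
#' fails with an error.
#'
#' @param trace an [intensity_trace()].
#' @param threshold detector units, or NULL for the mixture-based automatic
#'   threshold.
#' @param hysteresis dead-band width in detector units (>= 0).
#' @param seed seed for the auto-threshold mixture fit.
#' @return An object of class `state_sequence`: integer vector (0 unbound,
#'   1 bound) with attributes `threshold`, `hysteresis`, `dt`.
#' @export
idealize <- function(trace, threshold = NULL, hysteresis = 0, seed = 1L) {
  stopifnot(inherits(trace, "intensity_trace"))
  check_number(hysteresis, "hysteresis", 0)
  y <- trace$intensity
  if (is.null(threshold)) {
    fit <- tryCatch(fit_mixture(y, 2L, seed), error = function(e) NULL)
    sep <- if (is.null(fit)) 0 else
      (fit$means[2] - fit$means[1]) /
        sqrt((fit$sds[1]^2 + fit$sds[2]^2) / 2)
    if (is.null(fit) || !is.finite(sep) || sep < 2)
      stop_invalid(paste("cannot determine a threshold: trace values are not",
                         "bimodal; supply `threshold` explicitly"))
    threshold <- mean(fit$means)
  }
  hi <- threshold + hysteresis / 2
  lo <- threshold - hysteresis / 2
  n <- length(y)
  s <- integer(n)
  s[1] <- as.integer(y[1] > threshold)
  for (i in 2:n) {
    s[i] <- if (y[i] > hi) 1L else if (y[i] < lo) 0L else s[i - 1L]
  }
  structure(s, threshold = threshold, hysteresis = hysteresis,
            dt = trace_dt(trace), class = "state_sequence")
}

#' Dwell times from a state sequence
#'
#' Run lengths times the frame interval, per state. The first and last runs
#' are censored (their true start/end is unobserved) and are excluded from
#' rate fits by default. The durations of all runs, censored included, sum
#' exactly to the trace duration.
#'
#' @param states a `state_sequence` from [idealize()].
#' @return An object of class `dwell_set`: data frame (`state`,
#'   `duration_s`, `censored`) with attribute `dt`.
#' @export
dwells <- function(states) {
  stopifnot(inherits(states, "state_sequence"))
  dt <- attr(states, "dt")
  r <- rle(as.integer(states))
  n_runs <- length(r$lengths)
  structure(data.frame(
    state = ifelse(r$values == 1L, "bound", "unbound"),
    duration_s = r$lengths * dt,
    censored = seq_len(n_runs) %in% c(1L, n_runs)),
    dt = dt, class = c("dwell_set", "data.frame"))
}

#' Construct a dwell set directly
#'
#' For use with externally generated (e.g. simulated) dwell times.
#'
#' @param bound_s,unbound_s dwell durations in seconds.
#' @param dt frame interval the dwells were sampled at (attribute only).
#' @return A `dwell_set`.
#' @export
dwell_set <- function(bound_s, unbound_s, dt = NA_real_) {
  structure(data.frame(
    state = c(rep("bound", length(bound_s)), rep("unbound", length(unbound_s))),
    duration_s = c(bound_s, unbound_s),
    censored = FALSE),
    dt = dt, class = c("dwell_set", "data.frame"))
}

#' First-order binding rate constants from dwell times
#'
#' Exponential maximum likelihood on the uncensored dwells:
#' `k_off = 1 / mean(bound dwells)`; the pseudo-first-order binding rate is
#' `1 / mean(unbound dwells)` and `k_on` is that rate divided by the ligand
#' concentration. `K_D = k_off / k_on` by definition. Percentile bootstrap
#' confidence intervals are computed over seeded resamples. A histogram
#' curve-fit mode (exponential fit to Freedman-Diaconis binned counts) is
#' available for comparison.
#'
#' @param dwellset a [dwells()] result (or [dwell_set()]).
#' @param concentration ligand concentration in M (> 0); required because
#'   the observed binding rate is concentration-scaled.
#' @param include_censored include censored dwells (biases rates; default
#'   FALSE).
#' @param method `"mle"` (default) or `"histogram"`.
#' @param n_boot bootstrap resamples for the confidence intervals.
#' @param seed bootstrap seed.
#' @param conf confidence level.
#' @return An object of class `kinetics_fit`: `k_on` (M^-1 s^-1), `k_off`
#'   (s^-1), `K_D` (M), `concentration`, `tau_bound`, `tau_unbound`,
#'   `n_bound`, `n_unbound`, `ci` (percentile intervals), `method`.
#' @export
fit_rates <- function(dwellset, concentration, include_censored = FALSE,
                      method = c("mle", "histogram"), n_boot = 1000L,
                      seed = 1L, conf = 0.95) {
  stopifnot(inherits(dwellset, "dwell_set") || is.data.frame(dwellset))
  method <- match.arg(method)
  check_number(concentration, "concentration", 0, strict_lower = TRUE)
  keep <- if (include_censored) rep(TRUE, nrow(dwellset)) else !dwellset$censored
  b <- dwellset$duration_s[keep & dwellset$state == "bound"]
  u <- dwellset$duration_s[keep & dwellset$state == "unbound"]
  if (length(b) < 10L || length(u) < 10L)
    stop_invalid("need >= 10 uncensored dwells per state (got %d bound, %d unbound)",
                 length(b), length(u))
  est <- function(bb, uu) {
    tb <- mean_dwell(bb, method)
    tu <- mean_dwell(uu, method)
    c(k_off = 1 / tb, k_obs = 1 / tu)
  }
  point <- est(b, u)
  k_off <- unname(point["k_off"])
  k_on <- unname(point["k_obs"]) / concentration
  boot <- withr::with_seed(as.integer(seed), {
    t(replicate(n_boot, {
      e <- est(sample(b, replace = TRUE), sample(u, replace = TRUE))
      c(e["k_off"], e["k_obs"] / concentration)
    }))
  })
  alpha <- (1 - conf) / 2
  ci <- rbind(k_off = stats::quantile(boot[, 1], c(alpha, 1 - alpha)),
              k_on = stats::quantile(boot[, 2], c(alpha, 1 - alpha)),
              K_D = stats::quantile(boot[, 1] / boot[, 2], c(alpha, 1 - alpha)))
  structure(list(k_on = k_on, k_off = k_off, K_D = k_off / k_on,
                 concentration = concentration,
                 tau_bound = 1 / k_off,
                 tau_unbound = 1 / unname(point["k_obs"]),
                 n_bound = length(b), n_unbound = length(u),
                 ci = ci, conf = conf, method = method,
                 include_censored = include_censored),
            class = "kinetics_fit")
}

mean_dwell <- function(x, method) {
  if (method == "mle") return(mean(x))
  # histogram mode: exponential decay fit to binned counts
  h <- graphics::hist(x, breaks = "FD", plot = FALSE)
  mids <- h$mids[h$counts > 0]
  counts <- h$counts[h$counts > 0]
  if (length(mids) < 3L) return(mean(x))
  fit <- stats::lm(log(counts) ~ mids)
  rate <- -unname(stats::coef(fit)[2])
  if (!is.finite(rate) || rate <= 0) mean(x) else 1 / rate
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("<kinetics_fit> (%s%s)\n", x$method,
              if (x$include_censored) ", censored included" else ""))
  cat(sprintf("  k_on  = %.4g M^-1 s^-1   [%.4g, %.4g]\n",
              x$k_on, x$ci["k_on", 1], x$ci["k_on", 2]))
  cat(sprintf("  k_off = %.4g s^-1        [%.4g, %.4g]\n",
              x$k_off, x$ci["k_off", 1], x$ci["k_off", 2]))
  cat(sprintf("  K_D   = %.4g M           [%.4g, %.4g]\n",
              x$K_D, x$ci["K_D", 1], x$ci["K_D", 2]))
  cat(sprintf("  dwells: %d bound, %d unbound at %.4g M ligand\n",
              x$n_bound, x$n_unbound, x$concentration))
  invisible(x)
}

#' @export
coef.kinetics_fit <- function(object, ...) {
  c(k_on = object$k_on, k_off = object$k_off, K_D = object$K_D)
}

#' @export
confint.kinetics_fit <- function(object, parm, level, ...) object$ci

#' One-step change-point detection
#'
#' Exhaustive single-change-point least squares: for every split the trace
#' is fitted by two constant levels and the split with minimum residual sum
#' of squares is selected. The step is reported only if the level difference
#' exceeds `gate` times the pooled residual standard deviation; upward and
#' downward steps are both detected and the direction reported.
#'
#' @param trace an [intensity_trace()] of length >= 5.
#' @param gate significance gate in pooled-sd units (default 3).
#' @param min_segment smallest allowed segment length in frames.
#' @return An object of class `step_fit` (`step_frame`, `step_time_s`,
#'   `pre_level`, `post_level`, `amplitude_ratio`, `direction`, `residual_sd`),
#'   or `NULL` when no significant step is present.
#' @export
detect_step <- function(trace, gate = 3, min_segment = 2L) {
  stopifnot(inherits(trace, "intensity_trace"))
  y <- trace$intensity
  n <- length(y)
  if (n < 5L) stop_invalid("trace too short for step detection (need >= 5)")
  ks <- min_segment:(n - min_segment)
  cs <- cumsum(y); cs2 <- cumsum(y^2)
  n1 <- ks; n2 <- n - ks
  s1 <- cs[ks]; s2 <- cs[n] - s1
  ss1 <- cs2[ks] - s1^2 / n1
  ss2 <- (cs2[n] - cs2[ks]) - s2^2 / n2
  sse <- ss1 + ss2
  k <- ks[which.min(sse)]
  m1 <- cs[k] / k
  m2 <- (cs[n] - cs[k]) / (n - k)
  pooled_sd <- sqrt(min(sse) / (n - 2))
  if (pooled_sd > 0 && abs(m2 - m1) <= gate * pooled_sd) return(NULL)
  structure(list(step_frame = k + 1L,          # first frame of the new level
                 step_time_s = trace$time_s[k + 1L],
                 pre_level = m1, post_level = m2,
                 amplitude_ratio = m2 / m1,
                 direction = if (m2 > m1) "up" else "down",
                 residual_sd = pooled_sd, n = n, gate = gate),
            class = "step_fit")
}

#' @export
print.step_fit <- function(x, ...) {
  cat(sprintf("<step_fit> %s step at frame %d (t = %.4g s): %.4g -> %.4g (ratio %.3f)\n",
              x$direction, x$step_frame, x$step_time_s, x$pre_level,
              x$post_level, x$amplitude_ratio))
  invisible(x)
}

#' @export
coef.step_fit <- function(object, ...) {
  c(step_frame = object$step_frame, pre_level = object$pre_level,
    post_level = object$post_level)
}
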