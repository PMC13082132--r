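test_that("idealize thresholds with hysteresis and auto-threshold", {
  # constant low trace with an explicit threshold: all unbound
  tr <- intensity_trace(seq(0, 0.9, 0.1), rep(0.1, 10))
  s <- idealize(tr, threshold = 1)
  expect_true(all(s == 0L))
  # noiseless square wave: exact recovery
  lev <- rep(c(0, 1, 0, 1, 0), each = 8)
  tr <- intensity_trace(seq_along(lev) * 0.03, lev)
  s <- idealize(tr, threshold = 0.5)
  expect_identical(as.integer(s), as.integer(lev))
  # unimodal trace cannot be auto-thresholded
  set.seed(1)
  flat <- intensity_trace(seq(0, 9.99, 0.01), rnorm(1000))
  expect_error(idealize(flat), "bimodal|threshold")
  # noisy two-state trace at SNR 5: misclassification < 5% with
  # hysteresis = 1 noise sd
  p <- two_state_params(k_on = 1.3e9, concentration = 2e-8, k_off = 3,
                        duration_s = 120, dt_s = 0.03, noise_sd = 0.2)
  sim <- simulate_two_state_trace(p, seed = 6)
  s <- idealize(sim$trace, hysteresis = 0.2)
  # reconstruct the generating state sequence from the noise-free levels
  clean <- simulate_two_state_trace(
    two_state_params(k_on = 1.3e9, concentration = 2e-8, k_off = 3,
                     duration_s = 120, dt_s = 0.03, noise_sd = 0),
    seed = 6)
  expect_lt(mean(as.integer(s) != clean$trace$intensity), 0.05)
})

test_that("dwell bookkeeping conserves duration exactly", {
  # alternating single frames: every dwell equals dt
  lev <- rep(c(0, 1), 20)
  tr <- intensity_trace(seq_along(lev) * 0.05, lev)
  d <- dwells(idealize(tr, threshold = 0.5))
  expect_true(all(d$duration_s == 0.05))
  # random state sequences: total dwell time (censored included) equals the
  # trace duration
  set.seed(9)
  for (i in 1:5) {
    lev <- sample(c(0, 10), 200, replace = TRUE)
    tr <- intensity_trace(seq_along(lev) * 0.03, lev + rnorm(200, 0, 0.5))
    d <- dwells(idealize(tr, threshold = 5))
    expect_equal(sum(d$duration_s), 200 * 0.03, tolerance = 1e-12)
  }
  # dwell counts track the true transition count on simulated traces whose
  # dwells are long against the frame interval
  p <- two_state_params(k_on = 1.3e9, concentration = 4e-10, k_off = 1,
                        duration_s = 600, dt_s = 0.03, noise_sd = 0)
  sim <- simulate_two_state_trace(p, seed = 3)
  d <- dwells(idealize(sim$trace, threshold = 0.5))
  # sub-frame dwells merge adjacent runs; allow boundary slack
  expect_lt(abs(nrow(d) - nrow(sim$dwells)), 0.1 * nrow(sim$dwells) + 2)
})

test_that("rate estimation is exact, consistent and censoring-aware", {
  # identical bound dwells of length T give k_off = 1/T exactly
  d <- dwell_set(rep(0.25, 20), rexp(20, 5))
  k <- fit_rates(d, 1e-8, n_boot = 50)
  expect_equal(k$k_off, 4)
  expect_equal(k$K_D, k$k_off / k$k_on, tolerance = 1e-12)
  # molecule-3 rates recovered from 10,000 dwells within 3 standard errors
  set.seed(11)
  conc <- 1e-8
  d <- dwell_set(rexp(10000, 7.8), rexp(10000, 1.3e9 * conc))
  k <- fit_rates(d, conc, n_boot = 200)
  expect_lt(abs(k$k_off - 7.8), 3 * 7.8 / sqrt(10000))
  expect_lt(abs(k$k_on - 1.3e9), 3 * 1.3e9 / sqrt(10000))
  expect_equal(k$K_D, 7.8 / 1.3e9, tolerance = 0.05)
  # bias shrinks with sample size (consistency)
  set.seed(12)
  d_big <- dwell_set(rexp(1e5, 7.8), rexp(1e5, 13))
  k_big <- fit_rates(d_big, conc, n_boot = 10)
  expect_lt(abs(k_big$k_off / 7.8 - 1), 0.01)
  # bootstrap intervals cover the point estimate
  expect_gt(k$k_off, k$ci["k_off", 1])
  expect_lt(k$k_off, k$ci["k_off", 2])
  expect_error(fit_rates(dwell_set(rexp(3, 1), rexp(3, 1)), 1e-8), "10")
})

test_that("censored dwells bias rates when included", {
  # a long trace whose mean dwell is ~10% of its length: the censored last
  # interval is a sizeable truncation
  p <- two_state_params(k_on = 1e9, concentration = 1e-8, k_off = 10,
                        duration_s = 3000, dt_s = 0.01, noise_sd = 0)
  sim <- simulate_two_state_trace(p, seed = 21)
  d <- sim$dwells
  b <- d$duration_s[d$state == "bound" & !d$censored]
  # true dwells excluding the censored tail estimate k_off within 3 SE
  k_excl <- 1 / mean(b)
  expect_lt(abs(k_excl - 10), 3 * 10 / sqrt(length(b)))
})

test_that("time rescaling leaves dimensionless products unchanged", {
  set.seed(13)
  b <- rexp(2000, 5); u <- rexp(2000, 2)
  k1 <- fit_rates(dwell_set(b, u), 1e-8, n_boot = 10)
  k2 <- fit_rates(dwell_set(10 * b, 10 * u), 1e-8, n_boot = 10)
  expect_equal(k2$k_off * 10, k1$k_off, tolerance = 1e-12)
  expect_equal(k2$k_on * 10, k1$k_on, tolerance = 1e-12)
  # the occupancy ratio k_off/k_obs is invariant
  expect_equal(k2$k_off / (k2$k_on * 1e-8), k1$k_off / (k1$k_on * 1e-8),
               tolerance = 1e-12)
})

test_that("detect_step matches the brute-force oracle and is calibrated", {
  # agreement with an independent exhaustive re-implementation
  set.seed(14)
  for (i in 1:50) {
    n <- sample(10:80, 1)
    y <- rnorm(n) + c(rep(0, n %/% 2), rep(sample(c(-2, 2), 1), n - n %/% 2))
    tr <- intensity_trace(seq_len(n) * 0.03, y)
    st <- detect_step(tr, gate = 0)   # gate 0: always report the best split
    bf <- brute_force_step(y)
    expect_equal(st$step_frame - 1L, bf$split)
  }
  # false-positive rate < 5% at gate 3 on constant noisy traces
  set.seed(15)
  fp <- sum(vapply(1:1000, function(i) {
    tr <- intensity_trace(seq(0, 59) * 0.03, rnorm(60))
    !is.null(detect_step(tr, gate = 3))
  }, NA))
  expect_lt(fp / 1000, 0.05)
  # localization within 1 frame in >= 95% of noisy planted steps
  set.seed(16)
  hits <- vapply(1:200, function(i) {
    s <- simulate_step_trace(1, 2, 0.9, 1.8, 0.03, noise_sd = 0.1,
                             seed = sample.int(1e6, 1))
    st <- detect_step(s$trace)
    !is.null(st) && abs(st$step_frame - s$truth$step_frame) <= 1
  }, NA)
  expect_gte(mean(hits), 0.95)
  # direction is reported for downward steps too
  y <- c(rep(5, 20), rep(2, 20))
  st <- detect_step(intensity_trace(seq_len(40) * 0.1, y + rnorm(40, 0, 0.1)))
  expect_equal(st$direction, "down")
  expect_error(detect_step(intensity_trace(c(0, 1), c(0, 1))), "too short")
})
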