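test_that("hyperspectral generator renders spots with correct spectra", {
  # empty scene, zero noise: constant background
  res <- simulate_hyperspectral_stack(scene_spec(16, 100),
                                      species_polystyrene(),
                                      noise_spec(background = 2),
                                      c(3000, 3055))
  expect_true(all(res$stack$data == 2))
  expect_equal(nrow(res$truth), 0)
  # one polystyrene spot: spectral argmax at 3055
  sc <- ps_scene(1500, 1500)
  wn <- seq(2950, 3150, 5)
  res <- simulate_hyperspectral_stack(sc, species_polystyrene(),
                                      noise_spec(), wn)
  center_px <- res$stack$data[16, 16, ]
  expect_equal(wn[which.max(center_px)], 3055)
  # peak amplitude equals contrast_per_kda * mass at the band maximum
  expect_equal(max(attr(res$truth, "band_amplitudes")), 1 * 100)
  # unknown species rejected
  bad <- scene_spec(16, 100, data.frame(x_nm = 500, y_nm = 500,
                                        species = "unobtainium"))
  expect_error(simulate_hyperspectral_stack(bad, species_polystyrene(),
                                            noise_spec(), wn),
               "unknown species")
})

test_that("generators are bit-reproducible under a fixed seed", {
  sc <- ps_scene(c(900, 2100), c(1000, 2500))
  wn <- seq(3000, 3100, 10)
  a <- simulate_hyperspectral_stack(sc, species_polystyrene(),
                                    noise_spec(sd = 3, seed = 7), wn)
  b <- simulate_hyperspectral_stack(sc, species_polystyrene(),
                                    noise_spec(sd = 3, seed = 7), wn)
  expect_identical(a$stack$data, b$stack$data)
  m1 <- simulate_landing_movie(1, species_immunoglobulin(), 5, 0.1,
                               seed = 3, noise = noise_spec(sd = 1, seed = 4))
  m2 <- simulate_landing_movie(1, species_immunoglobulin(), 5, 0.1,
                               seed = 3, noise = noise_spec(sd = 1, seed = 4))
  expect_identical(m1$stack$data, m2$stack$data)
  expect_identical(m1$events, m2$events)
  t1 <- simulate_two_state_trace(two_state_params(noise_sd = 0.1), seed = 5)
  t2 <- simulate_two_state_trace(two_state_params(noise_sd = 0.1), seed = 5)
  expect_identical(t1$trace$intensity, t2$trace$intensity)
  expect_identical(t1$dwells, t2$dwells)
  c1 <- simulate_calibration_set(seed = 11)
  c2 <- simulate_calibration_set(seed = 11)
  expect_identical(c1$intensity, c2$intensity)
  s1 <- make_amide_spectrum(c(20, 50, 30), noise_sd = 0.01, seed = 2)
  s2 <- make_amide_spectrum(c(20, 50, 30), noise_sd = 0.01, seed = 2)
  expect_identical(s1$intensity, s2$intensity)
})

test_that("landing events follow the configured Poisson process", {
  # zero rate: no events
  m <- simulate_landing_movie(0, species_immunoglobulin(), 5, 0.1, seed = 1)
  expect_equal(nrow(m$events), 0)
  # mean count over replicates matches rate * duration (Poisson oracle);
  # withr scoping keeps each replicate's generator stream independent
  counts <- vapply(1:200, function(i) {
    nrow(simulate_landing_movie(1, species_immunoglobulin(), 100, 10,
                                scene = scene_spec(8, 100), seed = i)$events)
  }, 0)
  expect_lt(abs(mean(counts) - 100), 3 * sqrt(100 / 200))
  # dt >= duration rejected
  expect_error(simulate_landing_movie(1, species_immunoglobulin(), 1, 2),
               "dt")
  # overlap flag from pairwise distance against the PSF width
  set.seed(1)
  m <- simulate_landing_movie(5, species_immunoglobulin(), 20, 0.5,
                              scene = scene_spec(16, 100), seed = 42)
  ev <- m$events
  if (nrow(ev) >= 2) {
    d <- as.matrix(dist(cbind(ev$x_nm, ev$y_nm))); diag(d) <- Inf
    expect_identical(ev$overlap, unname(apply(d, 1, min) < 230))
  }
})

test_that("two-state traces have exponential dwells with the right moments", {
  # huge binding rate with no noise pins the trace at the bound level
  p <- two_state_params(k_on = 1e12, concentration = 1e-3, k_off = 1e-4,
                        duration_s = 3, bound_level = 5, unbound_level = 0)
  tr <- simulate_two_state_trace(p, seed = 2)
  expect_true(all(tr$trace$intensity == 5))
  # dwell moments: mean bound dwell = 1/k_off within 3 SE at large n
  p <- two_state_params(k_on = 1.3e9, concentration = 1e-8, k_off = 7.8,
                        duration_s = 3000, dt_s = 0.03)
  d <- simulate_two_state_trace(p, seed = 8)$dwells
  b <- d$duration_s[d$state == "bound" & !d$censored]
  u <- d$duration_s[d$state == "unbound" & !d$censored]
  expect_gt(length(b), 5000)
  expect_lt(abs(mean(b) - 1 / 7.8), 3 * sd(b) / sqrt(length(b)))
  # long-run bound occupancy matches the stationary distribution
  occ <- sum(b) / (sum(b) + sum(u))
  kc <- 1.3e9 * 1e-8
  p_stat <- kc / (kc + 7.8)
  expect_lt(abs(occ - p_stat), 0.02)
})

test_that("step traces and amide spectra encode their ground truth", {
  s <- simulate_step_trace(1, 2.23, 0.5, 1, 0.01)
  expect_equal(sort(unique(s$trace$intensity)), c(1, 2.23))
  expect_equal(s$trace$intensity[s$truth$step_frame - 1], 1)
  expect_equal(s$trace$intensity[s$truth$step_frame], 2.23)
  expect_error(simulate_step_trace(2, 1, 0.5, 1, 0.01), "post_level")
  expect_error(simulate_step_trace(1, 2, 1.5, 1, 0.01), "step time")

  # amide generator: area bookkeeping and fraction validation
  expect_error(make_amide_spectrum(c(50, 30, 10)), "sum to 100")
  sp <- make_amide_spectrum(c(100, 0, 0), ring_amplitude = 0)
  expect_equal(sp$wavenumber_cm1[which.max(sp$intensity)], 1656)
  # integrated area equals the configured total (unit structural area);
  # integrate on a wide grid to capture the Lorentzian tails
  wide <- make_amide_spectrum(c(100, 0, 0), ring_amplitude = 0,
                              wavenumber = seq(800, 2400, 1))
  expect_equal(sum(wide$intensity) * 1, 1, tolerance = 0.02)
  tr <- attr(make_amide_spectrum(c(24, 39, 37)), "truth")
  expect_equal(unname(tr$areas[c("alpha", "beta", "extended")]),
               c(0.24, 0.39, 0.37))
})

test_that("calibration sets have the configured first two moments", {
  cs <- simulate_calibration_set(masses_kda = c(100, 400), slope = 2,
                                 cv = 0.1, n = 500, seed = 3)
  for (m in c(100, 400)) {
    v <- cs$intensity[cs$mass_kda == m]
    expect_lt(abs(mean(v) - 2 * m), 3 * 0.1 * 2 * m / sqrt(500))
    expect_equal(sd(v), 0.1 * 2 * m, tolerance = 0.15)
  }
  # CV = 0 collapses onto the line exactly
  cs0 <- simulate_calibration_set(masses_kda = 150, slope = 1.5, cv = 0,
                                  n = 20, seed = 1)
  expect_true(all(cs0$intensity == 1.5 * 150))
})
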