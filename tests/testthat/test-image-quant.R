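test_that("fit_spot recovers noiseless Gaussian parameters exactly", {
  img <- ps_image(noise_sd = 0)
  rec <- fit_spot(img, c(1480, 1620), 100)
  expect_true(rec$converged)
  expect_equal(rec$x_nm, 1500, tolerance = 1e-6)
  expect_equal(rec$y_nm, 1600, tolerance = 1e-6)
  expect_equal(rec$amplitude, 100, tolerance = 1e-6)
  expect_equal(rec$sigma_nm, 230 / (2 * sqrt(2 * log(2))), tolerance = 1e-6)
  expect_equal(rec$integrated, 2 * pi * rec$amplitude * rec$sigma_nm^2)
  # linearity: scaling the image scales the amplitude
  rec2 <- fit_spot(3.7 * img, c(1480, 1620), 100)
  expect_equal(rec2$amplitude, 3.7 * rec$amplitude, tolerance = 1e-6)
  # constant offset goes to the background term, amplitude untouched
  rec3 <- fit_spot(img + 11, c(1480, 1620), 100)
  expect_equal(rec3$amplitude, rec$amplitude, tolerance = 1e-5)
  expect_equal(rec3$background, rec$background + 11, tolerance = 1e-5)
  expect_error(fit_spot(img[1:5, 1:5], c(100, 100), 100), "smaller than")
})

test_that("detect_spots finds planted spots and rejects blank fields", {
  sc <- scene_spec(64, 100, data.frame(
    x_nm = c(1000, 4500, 2500, 5200, 3000),
    y_nm = c(1200, 1000, 3300, 4800, 5600),
    species = "polystyrene"))
  res <- simulate_hyperspectral_stack(
    sc, species_polystyrene(contrast_per_kda = 1, mass_kda = 100),
    noise_spec(sd = 10, seed = 4), 3055)   # SNR 10
  spots <- detect_spots(res$stack$data[, , 1], 100)
  expect_equal(nrow(spots), 5)
  # every truth position matched within 1 pixel (100 nm)
  for (i in 1:5) {
    d <- sqrt((spots$x_nm - sc$spots$x_nm[i])^2 +
              (spots$y_nm - sc$spots$y_nm[i])^2)
    expect_lt(min(d), 100)
  }
  # blank pure-noise fields: no detections at min_snr = 5
  n_false <- sum(vapply(1:10, function(i) {
    set.seed(i)
    nrow(detect_spots(matrix(rnorm(256 * 256), 256, 256), 100))
  }, 0))
  expect_lte(n_false, 1)  # < 1 false positive per 10^6 pixels
})

test_that("unresolved pairs yield one flagged detection", {
  # two spots 0.4 FWHM (92 nm) apart merge into one detection with an
  # overlap flag; a single spot under identical noise is not flagged
  sc2 <- scene_spec(32, 100, data.frame(x_nm = c(1500, 1592),
                                        y_nm = c(1600, 1600),
                                        species = "polystyrene"))
  pair <- simulate_hyperspectral_stack(sc2, species_polystyrene(),
                                       noise_spec(sd = 0.2, seed = 2), 3055)
  s2 <- detect_spots(pair$stack$data[, , 1], 100)
  expect_equal(nrow(s2), 1)
  expect_true(s2$overlap)
  single <- ps_image(noise_sd = 0.2, seed = 2)
  s1 <- detect_spots(single, 100)
  expect_equal(nrow(s1), 1)
  expect_false(s1$overlap)
})

test_that("detection and fitting are translation-equivariant", {
  img <- ps_image(noise_sd = 0.5, seed = 9, x_nm = 1500, y_nm = 1600)
  d1 <- detect_spots(img, 100)
  shifted <- matrix(0, 32, 32)
  shifted[4:32, 4:32] <- img[1:29, 1:29]   # shift by +3 px in x and y
  d2 <- detect_spots(shifted, 100)
  expect_equal(nrow(d2), 1)
  expect_equal(d2$x_nm - d1$x_nm, 300, tolerance = 1e-6)
  expect_equal(d2$y_nm - d1$y_nm, 300, tolerance = 1e-6)
})

test_that("amplitude estimates are unbiased at SNR 10", {
  amps <- vapply(1:200, function(i)
    fit_spot(ps_image(noise_sd = 10, seed = i), c(1500, 1600), 100)$amplitude,
    0)
  expect_lt(abs(mean(amps) / 100 - 1), 0.02)
})

test_that("extract_spectrum reproduces species spectra at fixed position", {
  wn <- seq(2800, 3100, 10)
  # polystyrene argmax at 3055, immunoglobulin argmax at 2939 (nearest band)
  for (cfg in list(list(sp = species_polystyrene(), peak = 3055),
                   list(sp = species_immunoglobulin(mass_kda = 950),
                        peak = 2939))) {
    sc <- scene_spec(32, 100, data.frame(x_nm = 1500, y_nm = 1600,
                                         species = cfg$sp$name))
    res <- simulate_hyperspectral_stack(sc, cfg$sp, noise_spec(), wn)
    band <- which.max(apply(res$stack$data, 3, max))
    spot <- detect_spots(res$stack$data[, , band], 100)
    spec <- extract_spectrum(res$stack, spot[1, ])
    expect_equal(spec$wavenumber_cm1[which.max(spec$intensity)],
                 wn[which.min(abs(wn - cfg$peak))])
    # noiseless single species: cosine similarity > 0.999 with the truth
    truth <- species_spectrum(cfg$sp, wn)
    cosine <- sum(spec$intensity * truth) /
      sqrt(sum(spec$intensity^2) * sum(truth^2))
    expect_gt(cosine, 0.999)
  }
  # stack of zeros: all-zero spectrum
  z <- hyperspectral_stack(array(0, c(32, 32, 3)), c(3000, 3050, 3100), 100)
  spot <- fit_spot(ps_image(), c(1480, 1620), 100)
  expect_true(all(extract_spectrum(z, spot)$intensity == 0))
})

test_that("track_spot_trace follows landing and binding dynamics", {
  # constant movie: constant trace
  const <- time_lapse_stack(array(3, c(16, 16, 5)), 0.1, 100)
  tr <- track_spot_trace(const, c(700, 700))
  expect_true(all(abs(tr$intensity) < 1e-9))  # flat field has no spot shape
  # landing at a known frame steps the locked-position trace
  m <- simulate_landing_movie(0.5, species_immunoglobulin(), 10, 0.1,
                              scene_spec(32, 100),
                              noise_spec(sd = 5, seed = 3), seed = 9)
  ev <- m$events[1, ]
  tr <- track_spot_trace(m$stack, c(ev$x_nm, ev$y_nm))
  st <- detect_step(tr)
  expect_false(is.null(st))
  expect_lte(abs(st$step_frame - ev$frame), 1)
  # recovered two-state trace correlates with the generating levels
  p <- two_state_params(k_on = 1.3e9, concentration = 2e-8, k_off = 2,
                        duration_s = 30, dt_s = 0.03,
                        bound_level = 100, unbound_level = 0, noise_sd = 0)
  sim <- simulate_two_state_trace(p, seed = 4)
  sc <- scene_spec(24, 100)
  sigma <- 230 / (2 * sqrt(2 * log(2)))
  cube <- vapply(sim$trace$intensity, function(a)
    srpscat:::render_spot(24, 24, 100, 1100, 1200, a, sigma),
    matrix(0, 24, 24))
  cube <- cube + withr::with_seed(7, array(rnorm(length(cube), 0, 10),
                                           dim = dim(cube)))  # SNR 10
  stack <- time_lapse_stack(cube, 0.03, 100)
  tr2 <- track_spot_trace(stack, c(1100, 1200))
  expect_gt(cor(tr2$intensity, sim$trace$intensity), 0.95)
})

test_that("denoise hook obeys identity and sqrt(n) averaging laws", {
  stack <- time_lapse_stack(array(rnorm(16 * 16 * 40), c(16, 16, 40)), 0.1, 100)
  expect_identical(denoise_hook(stack, "none")$data, stack$data)
  expect_identical(denoise_hook(stack, "frame_average", 1)$data, stack$data)
  avg <- denoise_hook(stack, "frame_average", 4)
  # interior frames average exactly 4 independent unit-variance frames
  interior <- avg$data[, , 5:35]
  expect_equal(sd(as.vector(interior)), 0.5, tolerance = 0.05)
  expect_error(denoise_hook(stack, "wavelet"), "unknown denoise method")
})
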