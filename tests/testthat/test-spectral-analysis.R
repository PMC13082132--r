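test_that("lasso_unmix solves the penalized problem correctly", {
  lib <- ch_library()
  wn <- lib$wavenumber
  # a pixel equal to one reference gets coefficient 1 for it, 0 elsewhere
  co <- lasso_unmix(lib$spectra[, "polystyrene"], lib, lambda = 1e-4)
  expect_equal(unname(co["polystyrene"]), 1, tolerance = 1e-3)
  expect_lt(max(co[c("immunoglobulin", "protein")]), 1e-3)
  # lambda = 0 reduces to non-negative least squares (independent solver)
  set.seed(2)
  y <- as.numeric(lib$spectra %*% c(0.5, 0, 1.2)) + rnorm(length(wn), 0, 0.01)
  mine <- lasso_unmix(y, lib, lambda = 0)
  oracle <- pracma::lsqnonneg(lib$spectra, y)$x
  expect_lt(max(abs(mine - oracle)), 1e-6)
})

test_that("lasso path shrinks monotonically and matches glmnet", {
  # orthogonal two-reference library: coefficients shrink toward zero as
  # lambda grows
  wn <- seq(1000, 1100, 1)
  r1 <- c(rep(1, 50), rep(0, 51)); r2 <- c(rep(0, 50), rep(1, 51))
  lib <- reference_library(wn, cbind(a = r1, b = r2))
  y <- 0.8 * r1 + 0.3 * r2
  lambdas <- c(0, 1, 5, 20, 60)
  path <- t(vapply(lambdas, function(l) lasso_unmix(y, lib, lambda = l),
                   numeric(2)))
  expect_true(all(diff(path[, 1]) <= 1e-12))
  expect_true(all(diff(path[, 2]) <= 1e-12))
  expect_true(all(path >= 0))
  lib3 <- ch_library()
  set.seed(4)
  y3 <- as.numeric(lib3$spectra %*% c(0.7, 0.2, 0)) +
    rnorm(length(lib3$wavenumber), 0, 0.02)
  lam <- 0.05
  g <- glmnet::glmnet(lib3$spectra, y3,
                      lambda = lam / (2 * length(y3)), lower.limits = 0,
                      intercept = FALSE, standardize = FALSE, thresh = 1e-14)
  expect_lt(max(abs(lasso_unmix(y3, lib3, lambda = lam) -
                    as.numeric(g$beta))), 1e-6)
})

test_that("cross-validation picks a small lambda for clean mixtures", {
  lib <- ch_library()
  set.seed(6)
  y <- as.numeric(lib$spectra %*% c(0.6, 0.8, 0)) +
    rnorm(length(lib$wavenumber), 0, 0.01)
  cv <- select_lambda(y, lib, lambdas = c(0.001, 0.1, 10, 1000), seed = 2)
  expect_equal(nrow(cv), 4)
  # gross over-regularization must score worse than light penalties
  expect_lt(attr(cv, "best"), 1000)
  expect_gt(cv$cv_error[4], cv$cv_error[1])
})

test_that("pixel-wise unmixing assigns two-species scenes correctly", {
  wn <- seq(2850, 3100, 10)
  lib <- reference_library(wn, list(
    apoferritin = species_spectrum(species_protein(), wn),
    fibronectin = species_spectrum(species_immunoglobulin(), wn)))
  miss <- 0
  for (s in 1:20) {
    sc <- scene_spec(32, 100, data.frame(
      x_nm = c(900, 2200), y_nm = c(1000, 2300),
      species = c("protein", "immunoglobulin")))
    res <- simulate_hyperspectral_stack(
      sc, list(species_protein(mass_kda = 480),
               species_immunoglobulin(mass_kda = 440)),
      noise_spec(sd = 5, seed = s), wn)
    am <- lasso_unmix(res$stack, lib, lambda = 1)
    # dominant reference at each planted pixel
    p1 <- am$abundance[11, 10, ]; p2 <- am$abundance[24, 23, ]
    if (which.max(p1) != 1) miss <- miss + 1
    if (which.max(p2) != 2) miss <- miss + 1
  }
  expect_equal(miss, 0)
  # grid mismatch rejected
  expect_error(lasso_unmix(rnorm(10), lib), "grid")
})

test_that("amide deconvolution recovers planted secondary structure", {
  # pure alpha: all structural area in the helix band
  sp <- make_amide_spectrum(c(100, 0, 0), ring_amplitude = 0)
  f <- deconvolve_amide(sp$wavenumber_cm1, sp$intensity)
  expect_true(f$converged)
  expect_gt(f$fractions["alpha"], 97)
  expect_lt(f$fractions["beta"], 1)
  expect_equal(sum(f$fractions), 100, tolerance = 1e-6)
  # fraction recovery across compositions at 1% noise: mean error < 3 points
  grid <- expand.grid(a = c(15, 25, 40), b = c(20, 40, 60))
  errs <- c()
  for (i in seq_len(nrow(grid))) {
    fr <- c(grid$a[i], grid$b[i], 100 - grid$a[i] - grid$b[i])
    if (fr[3] < 5) next
    sp <- make_amide_spectrum(fr, noise_sd = 0.01, seed = 100 + i)
    f <- deconvolve_amide(sp$wavenumber_cm1, sp$intensity)
    expect_true(all(f$bands$center >= srpscat:::AMIDE_CENTERS - 5) &&
                all(f$bands$center <= srpscat:::AMIDE_CENTERS + 5))
    errs <- c(errs, abs(f$fractions - fr))
  }
  expect_lt(mean(errs), 3)
  # self-consistency: decompose -> regenerate -> decompose
  sp <- make_amide_spectrum(c(30, 50, 20), noise_sd = 0.01, seed = 7)
  f1 <- deconvolve_amide(sp$wavenumber_cm1, sp$intensity)
  f2 <- deconvolve_amide(sp$wavenumber_cm1, predict(f1))
  expect_lt(max(abs(f1$fractions - f2$fractions)), 1)
  expect_error(deconvolve_amide(seq(1640, 1700), rep(1, 61)), "cover")
})

test_that("C-H band classification separates immunoglobulins", {
  wn <- seq(2800, 3100, 1)
  ig <- species_spectrum(species_immunoglobulin(), wn)
  other <- species_spectrum(species_protein(), wn)
  expect_equal(classify_ch_band(wn, ig)$label, "immunoglobulin-like")
  expect_equal(classify_ch_band(wn, ig)$center_cm1, 2939, tolerance = 0.01)
  expect_equal(classify_ch_band(wn, other)$label, "non-immunoglobulin")
  expect_error(classify_ch_band(wn, rep(1, length(wn))), "no peak")
})

test_that("band ratios are scale-invariant and track DNA content", {
  wn <- seq(2800, 3100, 1)
  y <- species_spectrum(species_immunoglobulin(), wn)
  r <- band_ratio(wn, y, 2880, 2939)
  expect_equal(band_ratio(wn, 7.3 * y, 2880, 2939), r, tolerance = 1e-12)
  # two equal peaks give ratio 1
  y2 <- srpscat:::pseudo_voigt(wn, 2880, 30) +
    srpscat:::pseudo_voigt(wn, 2990, 30)
  expect_equal(band_ratio(wn, y2, 2880, 2990), 1, tolerance = 0.01)
  # DNA-containing capsids have a higher 2959/2930 ratio than empty ones
  # (sign test over seeds)
  wins <- 0
  for (s in 1:20) {
    noise <- withr::with_seed(s, rnorm(length(wn), 0, 0.005))
    empty <- species_spectrum(species_protein(), wn) + noise
    full <- species_spectrum(species_protein(), wn) +
      0.5 * species_spectrum(species_dna(), wn) + noise
    if (band_ratio(wn, full, 2959, 2930) >
        band_ratio(wn, empty, 2959, 2930)) wins <- wins + 1
  }
  expect_equal(wins, 20)
  expect_error(band_ratio(wn, y, 3200, 2939), "not on the grid")
  expect_error(band_ratio(wn, -y, 2880, 2939), "not positive")
})
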