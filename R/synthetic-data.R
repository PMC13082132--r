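#' Species specification for the synthetic microscope
#'
#' A species is a set of pseudo-Voigt Raman bands plus a linear mass-to-
#' contrast coefficient. The band envelope is normalized to unit maximum, so
#' a spot's peak amplitude equals `contrast_per_kda * mass_kda` at the
#' species' strongest band.
#'
#' @param name species label used in scenes and ground-truth tables.
#' @param peaks data frame with columns `center` (cm^-1), `fwhm` (cm^-1),
#'   `height` (relative, >= 0), `eta` (Lorentzian fraction in \[0, 1\]).
#' @param contrast_per_kda detector units of peak amplitude per kDa.
#' @param mass_kda molecular mass in kDa.
#' @return An object of class `species_spec`.
#' @export
species_spec <- function(name, peaks, contrast_per_kda = 1, mass_kda = 100) {
  stopifnot(is.character(name), length(name) == 1L)
  peaks <- as.data.frame(peaks)
  need <- c("center", "fwhm", "height")
  if (!all(need %in% names(peaks)))
    stop_invalid("peaks needs columns center, fwhm, height")
  if (is.null(peaks$eta)) peaks$eta <- 0.5
  if (any(peaks$fwhm <= 0)) stop_invalid("peak widths must be > 0")
  if (any(peaks$height < 0)) stop_invalid("peak heights must be >= 0")
  if (any(peaks$eta < 0 | peaks$eta > 1))
    stop_invalid("eta must lie in [0, 1]")
  check_number(contrast_per_kda, "contrast_per_kda", 0, strict_lower = TRUE)
  check_number(mass_kda, "mass_kda", 0, strict_lower = TRUE)
  structure(list(name = name, peaks = peaks,
                 contrast_per_kda = contrast_per_kda, mass_kda = mass_kda),
            class = "species_spec")
}

#' Band envelope of a species on a wavenumber grid
#' @param species a [species_spec()].
#' @param wavenumber grid in cm^-1.
#' @param normalize rescale to unit maximum (default TRUE).
#' @return numeric vector of relative intensities.
#' @export
species_spectrum <- function(species, wavenumber, normalize = TRUE) {
  pk <- species$peaks
  s <- numeric(length(wavenumber))
  for (i in seq_len(nrow(pk)))
    s <- s + pk$height[i] * pseudo_voigt(wavenumber, pk$center[i],
                                         pk$fwhm[i], pk$eta[i])
  if (normalize) {
    m <- max(s)
    if (m > 0) s <- s / m
  }
  s
}

#' Built-in species presets
#'
#' Band models used throughout the synthetic scenes: polystyrene beads
#' (aromatic C-H at 3055 cm^-1), immunoglobulins (CH3 stretch at 2939 cm^-1
#' with the 2880 cm^-1 shoulder), non-immunoglobulin proteins (2930 cm^-1),
#' and DNA (C-H stretch at 2959 cm^-1), matching the bands used for
#' classification and band-ratio readouts.
#'
#' @param contrast_per_kda,mass_kda forwarded to [species_spec()].
#' @return A [species_spec()].
#' @name species_presets
NULL

#' @rdname species_presets
#' @export
species_polystyrene <- function(contrast_per_kda = 1, mass_kda = 100) {
  species_spec("polystyrene",
               data.frame(center = 3055, fwhm = 22, height = 1, eta = 0.5),
               contrast_per_kda, mass_kda)
}

#' @rdname species_presets
#' @export
species_immunoglobulin <- function(contrast_per_kda = 1, mass_kda = 950) {
  species_spec("immunoglobulin",
               data.frame(center = c(2880, 2939), fwhm = c(45, 38),
                          height = c(0.55, 1), eta = 0.5),
               contrast_per_kda, mass_kda)
}

#' @rdname species_presets
#' @export
species_protein <- function(contrast_per_kda = 1, mass_kda = 66.5) {
  species_spec("protein",
               data.frame(center = c(2880, 2930), fwhm = c(45, 38),
                          height = c(0.75, 1), eta = 0.5),
               contrast_per_kda, mass_kda)
}

#' @rdname species_presets
#' @export
species_dna <- function(contrast_per_kda = 1, mass_kda = 1500) {
  species_spec("dna",
               data.frame(center = 2959, fwhm = 40, height = 1, eta = 0.5),
               contrast_per_kda, mass_kda)
}

#' Scene specification
#'
#' @param field_px integer c(ny, nx) field size in pixels (scalar = square).
#' @param pixel_size_nm pixel pitch in nm.
#' @param spots data frame with columns `x_nm`, `y_nm`, `species` (positions
#'   from the top-left pixel center); may be empty.
#' @param psf_fwhm_nm point-spread-function FWHM in nm (default 230, the
#'   instrument's stated spatial resolution).
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(field_px = 64, pixel_size_nm = 100,
                       spots = data.frame(x_nm = numeric(), y_nm = numeric(),
                                          species = character()),
                       psf_fwhm_nm = 230) {
  if (length(field_px) == 1L) field_px <- c(field_px, field_px)
  field_px <- as.integer(field_px)
  if (any(field_px < 4L)) stop_invalid("field must be at least 4 px")
  check_number(pixel_size_nm, "pixel_size_nm", 0, strict_lower = TRUE)
  check_number(psf_fwhm_nm, "psf_fwhm_nm", 0, strict_lower = TRUE)
  spots <- as.data.frame(spots)
  if (nrow(spots)) {
    lim <- (field_px - 1L) * pixel_size_nm
    if (any(spots$x_nm < 0 | spots$x_nm > lim[2] |
            spots$y_nm < 0 | spots$y_nm > lim[1]))
      stop_invalid("spot positions must lie inside the field")
  }
  structure(list(field_px = field_px, pixel_size_nm = pixel_size_nm,
                 spots = spots, psf_fwhm_nm = psf_fwhm_nm),
            class = "scene_spec")
}

#' Noise specification
#' @param background constant background level in detector units.
#' @param sd Gaussian readout noise standard deviation (shot-noise-limited
#'   surrogate) in detector units.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(background = 0, sd = 0, seed = 1L) {
  check_number(background, "background")
  check_number(sd, "sd", 0)
  check_number(seed, "seed")
  structure(list(background = background, sd = sd, seed = as.integer(seed)),
            class = "noise_spec")
}

# Render one Gaussian spot onto a field (matrix [ny, nx]).
render_spot <- function(ny, nx, pixel_size_nm, x_nm, y_nm, amplitude, sigma_nm) {
  x <- (seq_len(nx) - 1) * pixel_size_nm
  y <- (seq_len(ny) - 1) * pixel_size_nm
  gx <- exp(-((x - x_nm)^2) / (2 * sigma_nm^2))
  gy <- exp(-((y - y_nm)^2) / (2 * sigma_nm^2))
  amplitude * (gy %o% gx)
}

min_pair_dist <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(rep(Inf, n))
  d <- as.matrix(stats::dist(cbind(x, y)))
  diag(d) <- Inf
  apply(d, 1L, min)
}

#' Simulate a hyperspectral stack with ground truth
#'
#' Renders each spot as an isotropic 2D Gaussian of the scene's PSF whose
#' amplitude at wavenumber `v` is `contrast_per_kda * mass * spectrum(v)`
#' for its species, then adds constant background and Gaussian readout
#' noise. Pure function of (arguments, seed).
#'
#' @param scene a [scene_spec()]; its `spots$species` must name entries of
#'   `species`.
#' @param species list of [species_spec()] objects (or a single one).
#' @param noise a [noise_spec()].
#' @param wavenumber strictly increasing band axis in cm^-1.
#' @return A list with `stack` ([hyperspectral_stack()]) and `truth`, a data
#'   frame (spot id, position, species, mass, peak amplitude, minimum
#'   neighbour distance, overlap flag) carrying the per-band amplitude matrix
#'   as attribute `band_amplitudes`.
#' @export
simulate_hyperspectral_stack <- function(scene, species, noise, wavenumber) {
  stopifnot(inherits(scene, "scene_spec"), inherits(noise, "noise_spec"))
  if (inherits(species, "species_spec")) species <- list(species)
  if (any(diff(wavenumber) <= 0))
    stop_invalid("wavenumber axis must be strictly increasing")
  names(species) <- vapply(species, `[[`, "", "name")
  unknown <- setdiff(unique(scene$spots$species), names(species))
  if (length(unknown))
    stop_invalid("unknown species in scene: %s", paste(unknown, collapse = ", "))

  ny <- scene$field_px[1]; nx <- scene$field_px[2]
  nb <- length(wavenumber)
  sigma <- fwhm_to_sigma(scene$psf_fwhm_nm)
  cube <- array(noise$background, dim = c(ny, nx, nb))
  sp <- scene$spots
  amps <- matrix(0, nrow(sp), nb)
  if (nrow(sp)) {
    for (i in seq_len(nrow(sp))) {
      s <- species[[sp$species[i]]]
      amps[i, ] <- s$contrast_per_kda * s$mass_kda *
        species_spectrum(s, wavenumber)
      g <- render_spot(ny, nx, scene$pixel_size_nm, sp$x_nm[i], sp$y_nm[i],
                       1, sigma)
      for (b in seq_len(nb)) cube[, , b] <- cube[, , b] + amps[i, b] * g
    }
  }
  if (noise$sd > 0)
    cube <- cube + withr::with_seed(noise$seed,
      array(stats::rnorm(length(cube), 0, noise$sd), dim = dim(cube)))

  mind <- min_pair_dist(sp$x_nm, sp$y_nm)
  truth <- data.frame(spot = seq_len(nrow(sp)),
                      x_nm = sp$x_nm, y_nm = sp$y_nm,
                      species = sp$species,
                      mass_kda = vapply(sp$species,
                        function(nm) species[[nm]]$mass_kda, 0),
                      peak_amplitude = if (nrow(sp)) apply(amps, 1, max) else numeric(),
                      min_dist_nm = mind,
                      overlap = mind < scene$psf_fwhm_nm)
  attr(truth, "band_amplitudes") <- amps
  list(stack = hyperspectral_stack(cube, wavenumber, scene$pixel_size_nm),
       truth = truth)
}

#' Simulate a single-molecule landing movie
#'
#' Landing times follow a Poisson process of the given rate; positions are
#' uniform over the field; each landed molecule persists to the end of the
#' movie as a PSF-sized Gaussian spot of amplitude
#' `contrast_per_kda * mass`.
#'
#' @param rate arrival rate in events/s (>= 0).
#' @param species a [species_spec()]; the movie is recorded at the species'
#'   strongest band.
#' @param duration_s,dt_s movie length and frame interval in s (`dt < duration`).
#' @param scene a [scene_spec()] providing field geometry (its spot list is
#'   ignored).
#' @param noise a [noise_spec()].
#' @param seed integer seed for the event process (noise uses `noise$seed`).
#' @return list with `stack` ([time_lapse_stack()]) and `events` data frame
#'   (time, landing frame, position, amplitude, overlap flag for events
#'   within one PSF FWHM of another).
#' @export
simulate_landing_movie <- function(rate, species, duration_s, dt_s,
                                   scene = scene_spec(), noise = noise_spec(),
                                   seed = 1L) {
  check_number(rate, "rate", 0)
  check_number(duration_s, "duration_s", 0, strict_lower = TRUE)
  check_number(dt_s, "dt_s", 0, strict_lower = TRUE)
  if (dt_s >= duration_s) stop_invalid("dt must be smaller than duration")
  stopifnot(inherits(species, "species_spec"), inherits(scene, "scene_spec"))
  n_frames <- max(2L, as.integer(round(duration_s / dt_s)))
  ny <- scene$field_px[1]; nx <- scene$field_px[2]
  lim <- (scene$field_px - 1L) * scene$pixel_size_nm
  ev <- withr::with_seed(as.integer(seed), {
    n <- stats::rpois(1L, rate * duration_s)
    data.frame(time_s = sort(stats::runif(n, 0, duration_s)),
               x_nm = stats::runif(n, 0, lim[2]),
               y_nm = stats::runif(n, 0, lim[1]))
  })
  ev$frame <- pmin(n_frames, floor(ev$time_s / dt_s) + 1L)
  ev$amplitude <- rep(species$contrast_per_kda * species$mass_kda, nrow(ev))
  mind <- min_pair_dist(ev$x_nm, ev$y_nm)
  ev$overlap <- mind < scene$psf_fwhm_nm

  sigma <- fwhm_to_sigma(scene$psf_fwhm_nm)
  cube <- array(noise$background, dim = c(ny, nx, n_frames))
  if (nrow(ev)) {
    for (i in seq_len(nrow(ev))) {
      g <- render_spot(ny, nx, scene$pixel_size_nm, ev$x_nm[i], ev$y_nm[i],
                       ev$amplitude[i], sigma)
      for (f in ev$frame[i]:n_frames) cube[, , f] <- cube[, , f] + g
    }
  }
  if (noise$sd > 0)
    cube <- cube + withr::with_seed(noise$seed,
      array(stats::rnorm(length(cube), 0, noise$sd), dim = dim(cube)))
  list(stack = time_lapse_stack(cube, dt_s, scene$pixel_size_nm),
       events = ev)
}

#' Two-state binding parameters
#'
#' First-order binding kinetics: unbound -> bound at rate `k_on *
#' concentration`, bound -> unbound at rate `k_off`.
#'
#' @param k_on association rate constant in M^-1 s^-1.
#' @param concentration ligand concentration in M.
#' @param k_off dissociation rate constant in s^-1.
#' @param dt_s,duration_s frame interval and trace duration in s.
#' @param bound_level,unbound_level intensity levels in detector units
#'   (`bound_level > unbound_level`).
#' @param noise_sd additive Gaussian noise sd in detector units.
#' @return An object of class `two_state_params`.
#' @export
two_state_params <- function(k_on = 1.3e9, concentration = 1e-8, k_off = 7.8,
                             dt_s = 0.03, duration_s = 60,
                             bound_level = 1, unbound_level = 0,
                             noise_sd = 0) {
  for (nm in c("k_on", "concentration", "k_off", "dt_s", "duration_s"))
    check_number(get(nm), nm, 0, strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", 0)
  if (bound_level <= unbound_level)
    stop_invalid("bound_level must exceed unbound_level")
  structure(as.list(environment())[c("k_on", "concentration", "k_off",
                                     "dt_s", "duration_s", "bound_level",
                                     "unbound_level", "noise_sd")],
            class = "two_state_params")
}

#' Simulate a two-state binding trace
#'
#' Exact continuous-time Markov chain with exponential waiting times, point-
#' sampled on the frame grid, plus additive Gaussian noise. The initial state
#' is drawn from the stationary distribution.
#'
#' @param params a [two_state_params()].
#' @param seed integer seed.
#' @return list with `trace` ([intensity_trace()]) and `dwells`, the true
#'   (uncensored) sojourn table: columns `state` ("bound"/"unbound"),
#'   `duration_s`, `censored` (TRUE for the final, truncated sojourn).
#' @export
simulate_two_state_trace <- function(params, seed = 1L) {
  stopifnot(inherits(params, "two_state_params"))
  kon_c <- params$k_on * params$concentration
  koff <- params$k_off
  n <- max(2L, as.integer(round(params$duration_s / params$dt_s)))
  t_frame <- (seq_len(n) - 1L) * params$dt_s
  out <- withr::with_seed(as.integer(seed), {
    p_bound <- kon_c / (kon_c + koff)
    state <- if (stats::runif(1) < p_bound) 1L else 0L  # 1 = bound
    times <- numeric(0); states <- integer(0); durs <- numeric(0)
    t <- 0
    while (t < params$duration_s) {
      rate <- if (state == 1L) koff else kon_c
      tau <- stats::rexp(1L, rate)
      times <- c(times, t); states <- c(states, state); durs <- c(durs, tau)
      t <- t + tau
      state <- 1L - state
    }
    list(times = times, states = states, durs = durs)
  })
  # state at each frame time: last sojourn starting at or before the frame
  idx <- findInterval(t_frame, out$times)
  level <- ifelse(out$states[idx] == 1L, params$bound_level,
                  params$unbound_level)
  if (params$noise_sd > 0)
    level <- level + withr::with_seed(as.integer(seed) + 1L,
      stats::rnorm(n, 0, params$noise_sd))
  dwells <- data.frame(
    state = ifelse(out$states == 1L, "bound", "unbound"),
    duration_s = out$durs,
    censored = seq_along(out$durs) == length(out$durs))
  list(trace = intensity_trace(t_frame, level), dwells = dwells)
}

#' Simulate a single-step trace
#'
#' Piecewise-constant intensity with one upward step (a conformational
#' switch that increases mass) plus Gaussian noise.
#'
#' @param pre_level,post_level intensity levels (post > pre).
#' @param step_time_s step time, strictly inside `(0, duration_s)`.
#' @param duration_s,dt_s trace length and frame interval in s.
#' @param noise_sd additive Gaussian noise sd.
#' @param seed integer seed.
#' @return list with `trace` ([intensity_trace()]) and `truth` (step frame,
#'   time and levels).
#' @export
simulate_step_trace <- function(pre_level, post_level, step_time_s,
                                duration_s, dt_s, noise_sd = 0, seed = 1L) {
  if (post_level <= pre_level)
    stop_invalid("post_level must exceed pre_level (mass increases)")
  if (step_time_s <= 0 || step_time_s >= duration_s)
    stop_invalid("step time must lie strictly inside (0, duration)")
  n <- max(2L, as.integer(round(duration_s / dt_s)))
  t_frame <- (seq_len(n) - 1L) * dt_s
  level <- ifelse(t_frame < step_time_s, pre_level, post_level)
  if (noise_sd > 0)
    level <- level + withr::with_seed(as.integer(seed),
      stats::rnorm(n, 0, noise_sd))
  step_frame <- which(t_frame >= step_time_s)[1L]
  list(trace = intensity_trace(t_frame, level),
       truth = data.frame(step_frame = step_frame,
                          step_time_s = t_frame[step_frame],
                          pre_level = pre_level, post_level = post_level))
}

#' Reference amide-I secondary-structure compositions
#'
#' Structural fractions (alpha-helix, beta-sheet, extended; percent, summing
#' to 100) used for the alpha-synuclein aggregation states: beta-sheet rises
#' from 39% in oligomers to 59% in fibrils while alpha-helix falls from 24%
#' to 13%.
#'
#' @param state `"oligomer"` or `"fibril"`.
#' @return named numeric vector `c(alpha, beta, extended)` in percent.
#' @export
amide_composition <- function(state = c("oligomer", "fibril")) {
  state <- match.arg(state)
  switch(state,
         oligomer = c(alpha = 24, beta = 39, extended = 37),
         fibril   = c(alpha = 13, beta = 59, extended = 28))
}

# default component widths (FWHM, cm^-1) of the four amide-I bands
AMIDE_CENTERS <- c(ring = 1615, alpha = 1656, beta = 1671, extended = 1680)
AMIDE_WIDTHS  <- c(ring = 20, alpha = 26, beta = 18, extended = 14)

#' Synthesize an amide-I band spectrum
#'
#' Sum of four pseudo-Voigt bands (ring modes 1615, alpha-helix 1656,
#' beta-sheet 1671, extended 1680 cm^-1) whose structural band *areas* are
#' proportional to the requested fractions, plus Gaussian noise scaled to
#' the clean peak height.
#'
#' @param fractions numeric c(alpha, beta, extended) in percent, summing to
#'   100 (tolerance 0.1).
#' @param ring_amplitude ring-mode band area relative to the total
#'   structural area.
#' @param noise_sd noise standard deviation as a fraction of the clean peak
#'   maximum.
#' @param wavenumber grid in cm^-1 (default 1580-1720, 1 cm^-1).
#' @param seed integer seed.
#' @param widths named FWHMs (cm^-1) for ring/alpha/beta/extended.
#' @param eta Lorentzian mixing fraction of all bands.
#' @return data frame (`wavenumber_cm1`, `intensity`) with attribute `truth`
#'   (the configured fractions, areas and band table).
#' @export
make_amide_spectrum <- function(fractions, ring_amplitude = 0.15,
                                noise_sd = 0, wavenumber = seq(1580, 1720, 1),
                                seed = 1L, widths = AMIDE_WIDTHS, eta = 0.5) {
  fractions <- as.numeric(fractions)
  if (length(fractions) != 3L || any(fractions < 0))
    stop_invalid("fractions must be three non-negative percentages")
  if (abs(sum(fractions) - 100) > 0.1)
    stop_invalid("fractions must sum to 100 (got %.3f)", sum(fractions))
  areas <- c(ring = ring_amplitude, fractions / 100)
  names(areas) <- names(AMIDE_CENTERS)
  heights <- areas / pseudo_voigt_area(widths[names(areas)], eta)
  clean <- numeric(length(wavenumber))
  for (nm in names(areas))
    clean <- clean + heights[[nm]] *
      pseudo_voigt(wavenumber, AMIDE_CENTERS[[nm]], widths[[nm]], eta)
  y <- clean
  if (noise_sd > 0)
    y <- y + withr::with_seed(as.integer(seed),
      stats::rnorm(length(y), 0, noise_sd * max(clean)))
  out <- data.frame(wavenumber_cm1 = wavenumber, intensity = y)
  attr(out, "truth") <- list(fractions = stats::setNames(fractions,
                                                         c("alpha", "beta", "extended")),
                             areas = areas,
                             centers = AMIDE_CENTERS, widths = widths,
                             eta = eta, heights = heights)
  out
}

#' Simulate a mass-calibration intensity set
#'
#' For each calibrant mass, draws `n` per-molecule intensities from a
#' Gaussian centred on `intercept + slope * mass` with standard deviation
#' `cv * slope * mass`.
#'
#' @param masses_kda calibrant masses in kDa (default: the five-protein
#'   ladder 66.5-950 kDa).
#' @param slope intensity per kDa (> 0).
#' @param cv coefficient of variation of per-molecule intensity.
#' @param n samples per species.
#' @param seed integer seed.
#' @param intercept intensity offset (default 0).
#' @return data frame (`species`, `mass_kda`, `intensity`) with attribute
#'   `truth` (slope, intercept, cv, n).
#' @export
simulate_calibration_set <- function(masses_kda = c(66.5, 80, 150, 385, 950),
                                     slope = 1, cv = 0.1, n = 500, seed = 1L,
                                     intercept = 0) {
  if (!length(masses_kda) || any(masses_kda <= 0))
    stop_invalid("masses must be positive")
  check_number(slope, "slope", 0, strict_lower = TRUE)
  check_number(cv, "cv", 0)
  check_number(n, "n", 1)
  vals <- withr::with_seed(as.integer(seed), {
    lapply(masses_kda, function(m)
      stats::rnorm(n, intercept + slope * m, cv * slope * m))
  })
  out <- data.frame(
    species = rep(sprintf("%.1f kDa", masses_kda), each = n),
    mass_kda = rep(masses_kda, each = n),
    intensity = unlist(vals))
  attr(out, "truth") <- list(slope = slope, intercept = intercept,
                             cv = cv, n = n)
  out
}
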