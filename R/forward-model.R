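#' Optical configuration of the instrument
#'
#' Collects the beam and detection parameters of the forward model. The pump
#' and Stokes beams drive a stimulated Raman transition at
#' `pump_wavenumber - stokes_wavenumber`; the probe beam is detected
#' interferometrically against the field reflected at the substrate
#' interface. Pulsed excitation is summarized by a repetition rate and an
#' effective (chirped) pulse duration whose product is the duty cycle used to
#' convert time-averaged absorbed power into an in-pulse transient value.
#'
#' @param pump_wavenumber,stokes_wavenumber beam positions in cm^-1
#'   (`pump > stokes > 0`).
#' @param probe_wavelength probe wavelength in nm.
#' @param numerical_aperture detection NA.
#' @param pump_power,stokes_power,probe_power time-averaged powers in W.
#' @param modulation_frequency lock-in modulation frequency in Hz.
#' @param field_reflection_coefficient magnitude of the interface reference
#'   field relative to the incident field, in (0, 1].
#' @param substrate_refractive_index refractive index of the substrate.
#' @param cos_phi cosine of the interference phase between reference and
#'   scattered fields; 1 = fully constructive detection (default).
#' @param rep_rate_hz laser repetition rate in Hz.
#' @param pulse_duration_s effective pulse duration in s (chirped pulses in
#'   spectral-focusing operation are a few to tens of ps).
#' @param collection_efficiency dimensionless factor lumping objective
#'   collection and detection geometry into the scattered-field magnitude.
#' @return An object of class `optical_config`.
#' @export
optical_config <- function(pump_wavenumber = 3725,
                           stokes_wavenumber = 786,
                           probe_wavelength = 520,
                           numerical_aperture = 1.3,
                           pump_power = 0.02,
                           stokes_power = 0.02,
                           probe_power = 0.005,
                           modulation_frequency = 1e6,
                           field_reflection_coefficient = 0.122,
                           substrate_refractive_index = 1.7,
                           cos_phi = 1,
                           rep_rate_hz = 80e6,
                           pulse_duration_s = 10e-12,
                           collection_efficiency = 1) {
  check_number(pump_wavenumber, "pump_wavenumber", 0, strict_lower = TRUE)
  check_number(stokes_wavenumber, "stokes_wavenumber", 0, strict_lower = TRUE)
  if (pump_wavenumber <= stokes_wavenumber)
    stop_invalid("Raman shift pump - stokes must be positive")
  check_number(probe_wavelength, "probe_wavelength", 0, strict_lower = TRUE)
  check_number(numerical_aperture, "numerical_aperture", 0, strict_lower = TRUE)
  check_number(pump_power, "pump_power", 0)
  check_number(stokes_power, "stokes_power", 0)
  check_number(probe_power, "probe_power", 0)
  check_number(modulation_frequency, "modulation_frequency", 0)
  check_number(field_reflection_coefficient, "field_reflection_coefficient",
               0, 1, strict_lower = TRUE)
  check_number(substrate_refractive_index, "substrate_refractive_index", 0,
               strict_lower = TRUE)
  check_number(cos_phi, "cos_phi", -1, 1)
  check_number(rep_rate_hz, "rep_rate_hz", 0, strict_lower = TRUE)
  check_number(pulse_duration_s, "pulse_duration_s", 0, strict_lower = TRUE)
  check_number(collection_efficiency, "collection_efficiency", 0,
               strict_lower = TRUE)
  structure(as.list(environment()), class = "optical_config")
}

#' Particle (analyte) model
#'
#' Physical description of the scatterer: geometry, optical constants, thermal
#' response and a lumped vibrational absorption coefficient. The absorbed
#' power at band center is `absorption_coefficient * pump_power *
#' stokes_power` (W per W^2), a species property summarizing stimulated Raman
#' gain/loss energy deposition.
#'
#' @param diameter_nm particle diameter in nm.
#' @param refractive_index particle refractive index.
#' @param thermo_optic_coefficient dn/dT of the particle material in K^-1.
#' @param thermal_expansion_coefficient linear expansion coefficient in K^-1.
#' @param raman_band_cm1 band center of the addressed vibration in cm^-1.
#' @param absorption_coefficient lumped absorbed-power coefficient in W^-1.
#' @param mass_kda molecular mass in kDa (optional, `NA` if not applicable).
#' @return An object of class `particle_model`.
#' @export
particle_model <- function(diameter_nm,
                           refractive_index,
                           thermo_optic_coefficient = -2e-4,
                           thermal_expansion_coefficient = 1e-4,
                           raman_band_cm1 = 2939,
                           absorption_coefficient = 5e-6,
                           mass_kda = NA_real_) {
  check_number(diameter_nm, "diameter_nm", 0, strict_lower = TRUE)
  check_number(refractive_index, "refractive_index", 0, strict_lower = TRUE)
  check_number(thermo_optic_coefficient, "thermo_optic_coefficient")
  check_number(thermal_expansion_coefficient, "thermal_expansion_coefficient")
  check_number(raman_band_cm1, "raman_band_cm1", 0, strict_lower = TRUE)
  check_number(absorption_coefficient, "absorption_coefficient", 0)
  if (!is.na(mass_kda)) check_number(mass_kda, "mass_kda", 0, strict_lower = TRUE)
  structure(as.list(environment()), class = "particle_model")
}

#' IgM-like default particle
#'
#' A 950 kDa immunoglobulin M molecule modelled as a protein sphere
#' (density ~1.35 g/cm^3 gives d ~ 13 nm), with a CH3-stretch band at
#' 2939 cm^-1 and thermo-optic/expansion coefficients typical of organic
#' solids.
#' @return A [particle_model()].
#' @export
particle_igm <- function() {
  particle_model(diameter_nm = 13, refractive_index = 1.54,
                 thermo_optic_coefficient = -2e-4,
                 thermal_expansion_coefficient = 1e-4,
                 raman_band_cm1 = 2939,
                 absorption_coefficient = 5e-6,
                 mass_kda = 950)
}

#' Polystyrene nanoparticle model
#' @param diameter_nm particle diameter in nm (e.g. 29, 50 or 75 nm beads).
#' @return A [particle_model()] with n = 1.59 and the aromatic C-H band at
#'   3055 cm^-1.
#' @export
particle_polystyrene <- function(diameter_nm = 29) {
  particle_model(diameter_nm = diameter_nm, refractive_index = 1.59,
                 thermo_optic_coefficient = -1.2e-4,
                 thermal_expansion_coefficient = 7e-5,
                 raman_band_cm1 = 3055,
                 absorption_coefficient = 5e-6)
}

#' Surrounding medium model
#'
#' @param refractive_index medium refractive index (>= 1).
#' @param thermal_conductivity in W m^-1 K^-1.
#' @param thermo_optic_coefficient dn/dT of the medium in K^-1.
#' @param volumetric_heat_capacity in J m^-3 K^-1 (sets the thermal
#'   diffusivity used for the transient rise-time correction).
#' @return An object of class `medium_model`. `medium_water()` gives the
#'   aqueous defaults.
#' @export
medium_model <- function(refractive_index = 1.33,
                         thermal_conductivity = 0.6,
                         thermo_optic_coefficient = -1e-4,
                         volumetric_heat_capacity = 4.18e6) {
  check_number(refractive_index, "refractive_index", 1)
  check_number(thermal_conductivity, "thermal_conductivity", 0,
               strict_lower = TRUE)
  check_number(thermo_optic_coefficient, "thermo_optic_coefficient")
  check_number(volumetric_heat_capacity, "volumetric_heat_capacity", 0,
               strict_lower = TRUE)
  structure(as.list(environment()), class = "medium_model")
}

#' @rdname medium_model
#' @export
medium_water <- function() medium_model()

#' Polarizability volume of a small dielectric sphere
#'
#' Clausius-Mossotti polarizability `a^3 (m^2 - 1) / (m^2 + 2)` with
#' `a = d/2` and relative index `m = n_p / n_m`. Negative for particles less
#' refractive than the medium; zero when index-matched.
#'
#' @param diameter_nm sphere diameter in nm.
#' @param n_particle,n_medium refractive indices (> 0).
#' @return Polarizability volume in nm^3.
#' @export
polarizability <- function(diameter_nm, n_particle, n_medium) {
  check_number(diameter_nm, "diameter_nm", 0, strict_lower = TRUE)
  check_number(n_particle, "n_particle", 0, strict_lower = TRUE)
  check_number(n_medium, "n_medium", 0, strict_lower = TRUE)
  m2 <- (n_particle / n_medium)^2
  if (abs(m2 + 2) < .Machine$double.eps)
    stop_invalid("degenerate index combination (m^2 + 2 = 0)")
  (diameter_nm / 2)^3 * (m2 - 1) / (m2 + 2)
}

# Scattered-to-incident field magnitude ratio for a dipole of polarizability
# alpha (nm^3) probed at wavelength lambda (nm): |s| = eta * k^3 * |alpha|.
scattered_field <- function(alpha_nm3, optics) {
  k <- 2 * pi / optics$probe_wavelength
  optics$collection_efficiency * k^3 * abs(alpha_nm3)
}

#' Interferometric scattering contrast
#'
#' Evaluates the iSCAT contrast of a particle against the interface reference
#' field: `interference = 2 (|s|/|r|) cos(phi)` and
#' `scattering = (|s|/|r|)^2`, with `|s|` proportional to polarizability over
#' wavelength squared (`|s| = eta k^3 |alpha|`). The interference term scales
#' as d^3 and dominates for small particles; the pure scattering term scales
#' as d^6.
#'
#' @param particle a [particle_model()].
#' @param medium a [medium_model()].
#' @param optics an [optical_config()].
#' @return An object of class `signal_prediction` with the contrast fields
#'   populated (`interference_term`, `scattering_term`, `total_contrast`).
#' @export
iscat_contrast <- function(particle, medium, optics = optical_config()) {
  stopifnot(inherits(particle, "particle_model"),
            inherits(medium, "medium_model"),
            inherits(optics, "optical_config"))
  r <- optics$field_reflection_coefficient
  if (r == 0) stop_invalid("no reference field (|r| = 0)")
  alpha <- polarizability(particle$diameter_nm, particle$refractive_index,
                          medium$refractive_index)
  s_over_r <- scattered_field(alpha, optics) / r
  # sign of the interference term follows the sign of the polarizability
  interference <- 2 * s_over_r * sign(alpha) * optics$cos_phi
  scattering <- s_over_r^2
  signal_prediction(interference_term = interference,
                    scattering_term = scattering)
}

#' Photothermal temperature rise at a particle surface
#'
#' Steady-state point-source solution of heat conduction into the medium:
#' `dT = P_abs / (4 pi kappa a)`, evaluated at the particle surface. Linear
#' in absorbed power, inversely proportional to radius and conductivity.
#'
#' @param absorbed_power_w absorbed power in W (>= 0).
#' @param particle_radius_nm particle radius in nm.
#' @param medium a [medium_model()] supplying `thermal_conductivity`.
#' @return Temperature rise in K.
#' @export
srp_temperature_rise <- function(absorbed_power_w, particle_radius_nm,
                                 medium = medium_water()) {
  check_number(absorbed_power_w, "absorbed_power_w", 0)
  check_number(particle_radius_nm, "particle_radius_nm", 0, strict_lower = TRUE)
  stopifnot(inherits(medium, "medium_model"))
  a_m <- particle_radius_nm * 1e-9
  absorbed_power_w / (4 * pi * medium$thermal_conductivity * a_m)
}

#' Full SRPSCAT/SRS signal prediction
#'
#' Propagates the photothermal perturbation through the contrast model. The
#' time-averaged absorbed power is
#' `P_abs = absorption_coefficient * pump_power * stokes_power`; the
#' cycle-averaged temperature rise `delta_T` (which the lock-in demodulation
#' responds to) then perturbs the particle index by
#' `delta_n = dn/dT * delta_T` and the radius by
#' `delta_r = a * beta * delta_T`. The SRPSCAT modulation depth is the
#' relative change of the iSCAT contrast recomputed at the perturbed
#' parameters; the SRS modulation depth is the relative pump-intensity loss
#' `P_abs / pump_power`. Both are reported as lock-in amplitudes at the
#' configured modulation frequency. `delta_T_transient` additionally reports
#' the in-pulse peak temperature excursion using the excitation duty cycle
#' and an exponential thermal rise-time correction
#' `1 - exp(-t_pulse / tau)` with `tau = a^2 / D_medium`.
#'
#' @inheritParams iscat_contrast
#' @return An object of class `signal_prediction` with all fields populated:
#'   contrast terms, `delta_T` (K, cycle-averaged), `delta_T_transient` (K),
#'   `delta_n`, `delta_r_nm`, `srpscat_modulation_depth`,
#'   `srs_modulation_depth`.
#' @export
modulation_depths <- function(particle, medium = medium_water(),
                              optics = optical_config()) {
  stopifnot(inherits(particle, "particle_model"),
            inherits(medium, "medium_model"),
            inherits(optics, "optical_config"))
  base <- iscat_contrast(particle, medium, optics)
  if (base$total_contrast == 0)
    stop_invalid("baseline contrast is zero; modulation depth undefined")
  p_abs <- particle$absorption_coefficient * optics$pump_power *
    optics$stokes_power
  a <- particle$diameter_nm / 2
  dT <- srp_temperature_rise(p_abs, a, medium)

  # transient in-pulse rise: peak power over the duty cycle, limited by the
  # particle's thermal rise time
  duty <- optics$rep_rate_hz * optics$pulse_duration_s
  diffusivity <- medium$thermal_conductivity / medium$volumetric_heat_capacity
  tau <- (a * 1e-9)^2 / diffusivity
  rise <- 1 - exp(-optics$pulse_duration_s / tau)
  dT_transient <- if (duty > 0 && p_abs > 0)
    srp_temperature_rise(p_abs / duty, a, medium) * rise else 0

  dn <- particle$thermo_optic_coefficient * dT
  dr <- a * particle$thermal_expansion_coefficient * dT

  hot <- particle
  hot$refractive_index <- particle$refractive_index + dn
  hot$diameter_nm <- particle$diameter_nm + 2 * dr
  perturbed <- iscat_contrast(hot, medium, optics)
  srpscat <- abs(perturbed$total_contrast - base$total_contrast) /
    abs(base$total_contrast)
  srs <- if (optics$pump_power > 0) p_abs / optics$pump_power else 0

  signal_prediction(interference_term = base$interference_term,
                    scattering_term = base$scattering_term,
                    delta_T = dT, delta_T_transient = dT_transient,
                    delta_n = dn, delta_r_nm = dr,
                    srpscat_modulation_depth = srpscat,
                    srs_modulation_depth = srs)
}

signal_prediction <- function(interference_term, scattering_term,
                              delta_T = NA_real_, delta_T_transient = NA_real_,
                              delta_n = NA_real_, delta_r_nm = NA_real_,
                              srpscat_modulation_depth = NA_real_,
                              srs_modulation_depth = NA_real_) {
  structure(list(interference_term = interference_term,
                 scattering_term = scattering_term,
                 total_contrast = interference_term + scattering_term,
                 delta_T = delta_T, delta_T_transient = delta_T_transient,
                 delta_n = delta_n, delta_r_nm = delta_r_nm,
                 srpscat_modulation_depth = srpscat_modulation_depth,
                 srs_modulation_depth = srs_modulation_depth),
            class = "signal_prediction")
}

#' @export
print.signal_prediction <- function(x, ...) {
  cat("<signal_prediction>\n")
  cat(sprintf("  interference term : %+.4g\n", x$interference_term))
  cat(sprintf("  scattering term   : %.4g\n", x$scattering_term))
  cat(sprintf("  total contrast    : %+.4g\n", x$total_contrast))
  if (!is.na(x$delta_T)) {
    cat(sprintf("  delta_T (avg)     : %.4g K   (transient %.4g K)\n",
                x$delta_T, x$delta_T_transient))
    cat(sprintf("  delta_n           : %+.4g\n", x$delta_n))
    cat(sprintf("  delta_r           : %+.4g nm\n", x$delta_r_nm))
    cat(sprintf("  SRPSCAT depth     : %.4g\n", x$srpscat_modulation_depth))
    cat(sprintf("  SRS depth         : %.4g\n", x$srs_modulation_depth))
  }
  invisible(x)
}
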