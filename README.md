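# srpscat

Quantitative analysis for stimulated Raman photothermal interferometric
scattering (SRPSCAT) microscopy — label-free, vibrationally resolved
single-molecule imaging.

In SRPSCAT, a pump/Stokes pulse pair drives a Raman transition at
ω_p − ω_s; the deposited vibrational energy relaxes into heat, and the
resulting refractive-index change Δn and thermal expansion Δr modulate the
particle's interferometric scattering (iSCAT) contrast. Lock-in
demodulation turns this into chemically specific contrast with
single-protein sensitivity, enabling mass photometry with chemical
identification, single-protein secondary-structure readout, binding
kinetics, and conformational-switching movies.

This package is for microscopists and analysts working with such data (or
building such instruments): it provides the full analysis chain and a
seeded synthetic microscope so that every stage is testable, with ground
truth, on a plain laptop.

## What is implemented

| Stage | Core model / statistic |
|---|---|
| Forward model | Clausius–Mossotti polarizability α = a³(m²−1)/(m²+2); iSCAT contrast 2(\|s\|/\|r\|)cos φ + (\|s\|/\|r\|)²; ΔT = P_abs/(4πκa); SRPSCAT/SRS modulation depths |
| Synthetic microscope | Gaussian-PSF scenes (230 nm FWHM), pseudo-Voigt band spectra, Poisson landing events, exact two-state Markov traces, amide-I composites, calibration intensity sets — all seeded, all with ground truth |
| Image quantification | DoG detection + 2D Gaussian fits; locked-position (linear) spectrum & trace extraction; frame-average denoising hook |
| Mass calibration | EM Gaussian mixtures on raw intensities (k-means init, BIC helper, dimer flagging); OLS intensity–mass line; mass accuracy metrics; d³/d⁶ power-law fits |
| Spectral analysis | Non-negative LASSO unmixing by coordinate descent (with CV helper); four-band amide-I deconvolution (ring/α/β/extended) with identifiability-aware defaults; C–H band classification and band ratios |
| Kinetics | Threshold+hysteresis idealization; censoring-aware dwell bookkeeping; exponential MLE for k_off, k_on, K_D = k_off/k_on with bootstrap CIs; exhaustive single change-point detection |
| I/O & pipeline | 32-bit float multi-page TIFF + CSV sidecar axes; YAML/JSON run configs with hashes and explicit seeds; `run_pipeline()` stages and a thin CLI wrapper (`inst/scripts/srpscat`) |

## Worked example

```r
library(srpscat)

## 1. Forward model: an IgM-like molecule under default optics
modulation_depths(particle_igm())
#> <signal_prediction>
#>   interference term : +0.00081
#>   scattering term   : 1.64e-07
#>   total contrast    : +0.0008102
#>   delta_T (avg)     : 0.04081 K   (transient 1.704 K)
#>   delta_n           : -8.162e-06
#>   delta_r           : +2.653e-05 nm
#>   SRPSCAT depth     : 2.522e-05
#>   SRS depth         : 1e-07
```

The modulation depth of the vibrationally encoded signal (~10⁻⁵) sits two
orders of magnitude above the direct stimulated-Raman depth (~10⁻⁷): the
photothermal route is what makes the vibrational contrast detectable.

```r
## 2. Mass calibration on a simulated five-protein ladder (66.5-950 kDa,
##    CV 10%, n = 500 per species), then mass of an unknown analyte
calset <- simulate_calibration_set(seed = 1)
masses <- sort(unique(calset$mass_kda))
means  <- vapply(masses, function(m)
  fit_mixture(calset$intensity[calset$mass_kda == m], k = 1, seed = 1)$means, 0)
cal <- fit_calibration(means, masses)
cal
#> <mass_calibration> intensity = -0.4213 + 1.001 * mass[kDa]
#>   average error: 0.25%   mass accuracy: 1.09 kDa   (n = 5)

analyte <- simulate_calibration_set(masses_kda = 142.2, seed = 7)
estimate_mass(fit_mixture(analyte$intensity, 1, 1)$means, cal)
#> [1] 143.1
```

A 142.2 kDa analyte (the mass of a designed trimeric protein's compact
state) is recovered within 1% through the full histogram → mixture →
calibration → inversion chain.

```r
## 3. Secondary structure from a synthetic fibril amide-I spectrum (1% noise)
sp  <- make_amide_spectrum(amide_composition("fibril"), noise_sd = 0.01, seed = 1)
fit <- deconvolve_amide(sp$wavenumber_cm1, sp$intensity)
round(fit$fractions, 1)
#>    alpha     beta extended
#>     12.8     59.4     27.8
```

The four-band deconvolution recovers the planted fibril composition
(α 13%, β 59%, extended 28%) to a fraction of a percentage point.

```r
## 4. Binding kinetics from a noisy two-state trace (10 nM ligand)
sim   <- simulate_two_state_trace(two_state_params(noise_sd = 0.15,
                                                   duration_s = 600), seed = 1)
rates <- fit_rates(dwells(idealize(sim$trace, hysteresis = 0.15)),
                   concentration = 1e-8)
rates
#> <kinetics_fit> (mle)
#>   k_on  = 9.563e+08 M^-1 s^-1   [9.247e+08, 9.898e+08]
#>   k_off = 5.836 s^-1        [5.61, 6.059]
#>   K_D   = 6.103e-09 M           [5.799e-09, 6.414e-09]
#>   dwells: 2173 bound, 2173 unbound at 1e-08 M ligand
```

Frame-level estimates carry the expected dead-time bias (dwells shorter
than one 30 ms frame are unobservable, pulling both rates low), while the
equilibrium constant K_D ≈ 6.1 nM is recovered almost unbiased because the
biases largely cancel in the ratio; fitting the true continuous-time dwell
times recovers k_off = 7.8 s⁻¹ and k_on = 1.3×10⁹ M⁻¹s⁻¹ within sampling
error (see the test suite).

See `vignettes/srpscat-methods.Rmd` for the models, parameter choices and
their rationale.

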