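---
title: "Models and methods behind srpscat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind srpscat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srpscat)
```

# Scope

`srpscat` implements the quantitative machinery of vibrationally resolved
interferometric scattering microscopy (SRPSCAT): a stimulated Raman pump and
Stokes pair deposits energy at the Raman shift $\omega_p - \omega_s$, the
resulting photothermal perturbation modulates a particle's elastic
scattering, and lock-in demodulation of the iSCAT signal turns that
modulation into chemically specific single-molecule contrast. The package
covers the analytic forward model, a seeded synthetic microscope, spot-level
image quantification, intensity-to-mass calibration, spectral readouts
(unmixing, amide-I secondary structure, C-H classification), and
single-molecule kinetics. Everything runs on synthetic data with attached
ground truth, so every stage is testable without instrument access.

# The forward model

## Contrast

A small dielectric sphere of diameter $d$ and index $n_p$ in a medium of
index $n_m$ has Clausius-Mossotti polarizability volume

$$\alpha = \left(\frac{d}{2}\right)^3 \frac{m^2-1}{m^2+2},
\qquad m = n_p/n_m.$$

The detected iSCAT intensity against the interface reference field $|r|$
contains an interference term $2(|s|/|r|)\cos\varphi$ and a pure scattering
term $(|s|/|r|)^2$, with the scattered field magnitude modelled as
$|s| = \eta k^3 |\alpha|$ ($k = 2\pi/\lambda_{probe}$; $\eta$ a lumped
collection factor). The interference term scales as $d^3$ and dominates for
molecules and small nanoparticles; pure scattering falls off as $d^6$. The
interference phase is not observable in our data model, so
$\cos\varphi = 1$ (constructive detection) is the default; it is a field in
`optical_config()` because the positive $d^3$ intensity law observed for
29-75 nm polystyrene beads is reproduced under this convention.

## Photothermal response

Vibrational absorption is lumped into a per-species coefficient: the
time-averaged absorbed power is
$P_{abs} = c_{abs} P_{pump} P_{Stokes}$ (units W per W$^2$), an
approximation of stimulated Raman gain/loss energy deposition. Steady-state
conduction into the medium gives the surface temperature rise

$$\Delta T = \frac{P_{abs}}{4\pi\kappa a},$$

linear in power and inverse in radius $a$ and conductivity $\kappa$. The
perturbation propagates to the contrast through the particle's thermo-optic
coefficient ($\Delta n = (dn_p/dT)\,\Delta T$) and linear thermal expansion
($\Delta r = a\beta\Delta T$), and the SRPSCAT modulation depth is the
relative contrast change evaluated by finite difference,

$$m_{SRPSCAT} = \frac{|C(n_p+\Delta n,\ d+2\Delta r) - C(n_p, d)|}{|C(n_p, d)|},$$

reported as a lock-in amplitude at the modulation frequency. The SRS
comparator is the relative pump intensity loss $P_{abs}/P_{pump}$ — an
order-of-magnitude comparator only, not a full treatment of stimulated
Raman gain.

## Averaged versus transient temperature

Pulsed excitation concentrates the absorbed energy into a duty cycle
$D = f_{rep}\,\tau_{pulse}$ (defaults: 80 MHz, 10 ps chirped pulses, so
$D = 8\times10^{-4}$). Two temperature figures are therefore reported:

* `delta_T` — the cycle-averaged rise driving the demodulated response
  (lock-in detection averages over many pulse periods);
* `delta_T_transient` — the in-pulse peak,
  $\Delta T_{ss}(P_{abs}/D)\,(1 - e^{-\tau_{pulse}/\tau_{th}})$, where
  $\tau_{th} = a^2/D_{medium}$ is the particle's thermal rise time. For an
  IgM-sized particle $\tau_{th} \approx 0.3$ ns, so a 10 ps pulse reaches
  only a few percent of its steady-state excursion.

With the IgM-like defaults (`particle_igm()`: 13 nm protein sphere,
$dn_p/dT = -2\times10^{-4}\,$K$^{-1}$, $\beta = 10^{-4}\,$K$^{-1}$,
$c_{abs} = 5\times10^{-6}\,$W$^{-1}$ at 20 mW pump and Stokes), the model
gives an SRPSCAT modulation depth of order $10^{-5}$, an SRS depth of order
$10^{-7}$ (two orders lower), and a transient rise of order 1-10 K. These
order-of-magnitude statements are the model's intended accuracy: the exact
published figures derive from a full transient heat-transport computation
that is outside this package's scope, and the steady-state point-source
model cannot simultaneously pin all three numbers because
$\Delta T$ and $P_{abs}/P_{pump}$ are rigidly linked through $P_{abs}$. The
tests assert orders of magnitude, nothing tighter.

A deliberate simplification in the simulator: the per-particle modulation
depth is treated as a species property independent of $d$, so simulated
SRPSCAT amplitudes scale with the interference term, i.e. as $d^3$. This
reproduces the empirical intensity-diameter law; note the unresolved
tension with volume-scaling absorption, which would steepen the law.

# The synthetic microscope

Generators are pure functions of their parameters and an explicit integer
seed (never global state); identical calls are bit-identical, and each
returns machine-readable ground truth sufficient to score the downstream
stage.

* **Optics.** Isotropic 2D Gaussian PSF, FWHM 230 nm by default (the
  instrument's stated resolution); Airy rings are not modelled. Pixel pitch
  defaults to 100 nm, slightly finer than Nyquist for a 230 nm PSF.
* **Spectra.** Species are sets of pseudo-Voigt bands (default mixing 0.5,
  exposed per peak); built-ins cover polystyrene (3055 cm^-1),
  immunoglobulins (2939 cm^-1 with the 2880 cm^-1 shoulder), other proteins
  (2930 cm^-1) and DNA (2959 cm^-1). Band envelopes are normalized to unit
  maximum so a spot's peak amplitude is `contrast_per_kda * mass`.
* **Noise.** Additive Gaussian readout noise as a shot-noise surrogate.
  Lock-in demodulated signals are well approximated as Gaussian, and no
  photon budget is specified for the instrument, so Poisson counting is not
  emulated. No iSCAT speckle, stage drift, or focus wander; photobleaching
  does not apply to a label-free contrast.
* **Kinetics.** Two-state traces are exact continuous-time Markov chains
  (exponential waiting times thinned onto the frame grid, not per-frame
  Bernoulli draws), preserving the continuous-time model the rate fits
  assume. The initial state is drawn from the stationary distribution.
* **Calibration sets.** Per-molecule intensities are Gaussian with
  sd = CV x mean; the default calibrant ladder 66.5 / 80 / 150 / 385 / 950
  kDa represents the five-protein series (BSA, transferrin, IgG, secretory
  IgA, IgM) by sequence mass, and CV 10% with n = 500 per species matches
  counting a few hundred spots per histogram.

What passing tests on these data do *not* show: robustness to structured
backgrounds, drift, aggregation-state mixtures beyond the modelled dimer
peaks, or deviations of real band shapes from pseudo-Voigt.

# Image quantification

Detection band-passes the image with a difference of Gaussians
($\sigma_{PSF}/\sqrt2$ and $\sigma_{PSF}\sqrt2$), takes strict 8-neighbour
local maxima above `min_snr` robust standard deviations (median/MAD; spots
would bias moment-based estimates), and refines each candidate with a
least-squares isotropic Gaussian + constant background fit. Fits must
converge, clear the SNR threshold, and keep $\sigma$ inside
`sigma_bounds_nm` (0.5-2 x the PSF $\sigma$ by default). Candidates
converging within one PSF FWHM of a stronger detection are merged.

Positions are locked when amplitudes are re-read across bands or frames
(immobilized molecules do not move; per-band refits would distort spectra),
which reduces spectrum extraction and trace tracking to closed-form linear
least squares for amplitude and background — fast and free of convergence
failures. Pixel indices are 0-based; physical positions are nm from the
top-left pixel center.

Two molecules inside one PSF cannot be split into two detections; the
overlap flag instead fires when the fitted width is inflated
(> 1.15 $\sigma_{PSF}$) or the fit residual exceeds 1.5 x the image noise
floor (for near-noiseless data, 0.5% of the amplitude). The residual rule
resolves a 0.4-FWHM pair only when the model mismatch (~1-3% of amplitude)
exceeds the noise; at SNR 10 such pairs are genuinely indistinguishable
from single spots and are not flagged.

Per-spot "intensity" is reported both as fitted peak amplitude and as
integrated intensity $2\pi A\sigma^2$; the amplitude is the default
histogram statistic, since the published histograms do not define their
intensity measure.

# Mass calibration

Mixture fitting runs expectation-maximization on the raw per-spot
intensities (bin-free likelihood behaves better than curve-fitting binned
counts at a few hundred events), initialized by k-means from an explicit
seed, components reported sorted by mean, with a degenerate-variance guard.
`select_components()` scans k = 1..5 by BIC; the published analyses choose
k by inspection (three components for the IgM monomer/dimer/trimer
histogram), so k remains user-supplied. Components near twice the dominant
mean are flagged (`dimer_components()`) as protein dimers or two molecules
within the diffraction limit and should be excluded from calibration means.

The calibration line is ordinary least squares with a free intercept
(whether the published fits are constrained through the origin is not
stated; the intercept is reported so either convention can be checked).
Residuals are re-expressed in kDa through the slope; `average_error_pct` is
the mean relative deviation and `mass_accuracy_kda` the worst absolute
deviation. `estimate_mass()` inverts the line and flags non-positive
results. Power-law analysis regresses log intensity on log diameter.

# Spectral analysis

## Unmixing

`lasso_unmix()` minimizes
$\|y - R c\|^2 + \lambda \sum_i |c_i|$ subject to $c_i \ge 0$ by cyclic
coordinate descent (tolerance $10^{-12}$, cap $10^4$ sweeps).
Non-negativity is on by default because abundances are physical
concentrations. At $\lambda = 0$ the solver reduces to non-negative least
squares and is tested against an independent implementation. No $\lambda$
is published; it is a user parameter with a band-wise K-fold
cross-validation helper (`select_lambda()`).

## Amide-I deconvolution and identifiability

The amide-I band is decomposed into ring modes (1615 cm^-1), alpha-helix
(1656), beta-sheet (1671) and extended structures (1680), pseudo-Voigt
each; structural fractions are band areas over the summed structural area,
excluding the ring band (aromatic ring modes are not secondary structure —
without this exclusion fractions cannot sum to 100%).

The three structural components sit 9-15 cm^-1 apart with 14-26 cm^-1
widths, so they overlap heavily. A numerical experiment drove the default
estimator design: fitting centers (+-5 cm^-1), widths (8-40 cm^-1) and
per-band mixing freely, spectra differing only in their 1%-of-peak noise
realization return beta-sheet fractions spread over ~10 percentage points —
even when the optimizer is started at the true parameters, i.e. the spread
is statistical, not an optimization artifact. The fractions are simply not
identifiable at realistic noise under a free-shape model. The default
estimator therefore treats the component line shapes (width and mixing) as
known reference values — the same band library the generator uses, mirroring
the common practice of importing amide-I component parameters from
reference deconvolutions — and solves only the band amplitudes plus a
linear baseline, by non-negative linear least squares. This is deterministic,
unbiased on matched data, and reproduces planted fractions to well under one
percentage point at 1% noise. `refine = "centers"` adds bounded center
refinement by variable projection; `refine = "full"` restores the free-shape
fit for high-SNR exploratory use. The baseline is estimated jointly inside
the (linear) model rather than pre-subtracted from band-free margins,
because margin subtraction steals Lorentzian tail area and biases fractions
by 2-3 points.

## C-H region readouts

`classify_ch_band()` locates the dominant C-H peak by parabolic
interpolation and labels spectra immunoglobulin-like (2939 cm^-1) or not
(2930 cm^-1) with the midpoint 2934.5 cm^-1 as the boundary.
`band_ratio()` reports background-corrected intensity ratios (end-point
linear baseline), covering the 2880/2939 denaturation marker and the
2959/2930 DNA-content contrast of viral capsids.

# Kinetics

Idealization is threshold crossing with hysteresis; the automatic threshold
is the midpoint of a 2-component mixture fit of the trace values and
requires component separation of at least 2 pooled standard deviations
(below that the trace is effectively unimodal and the threshold is
refused). Dwells are run lengths times the frame interval; first and last
runs are censored and excluded from fits by default — including them
truncates long dwells and biases rates upward. Dwells shorter than one
frame are unobservable; no dead-time correction is applied (documented
limitation — at the defaults the mean dwell is several frames).

Rates use the closed-form exponential maximum-likelihood estimator:
$k_{off} = 1/\overline{t}_{bound}$, the pseudo-first-order binding rate
$1/\overline{t}_{unbound}$, and $k_{on}$ = that rate divided by the ligand
concentration, which must be supplied explicitly (published $k_{on}$ values
are concentration-normalized but the concentration is not printed; the
simulator default is 10 nM, giving ~77 ms mean unbound dwells at the
published rates, consistent with rapid binding at 30 ms frames). A
histogram curve-fit mode exists for comparison with the
exponential-histogram presentation. $K_D = k_{off}/k_{on}$ by definition.
Uncertainty comes from seeded percentile bootstrap (1000 resamples by
default).

`detect_step()` fits two constant levels at every split (vectorized via
cumulative sums — algebraically identical to the brute-force scan it is
tested against) and reports the minimum-SSE split only if the level
difference exceeds `gate` (default 3) pooled residual standard deviations;
both directions are detected. On white noise this gate yields a
false-positive rate far below 5%, and steps with 10% relative noise
localize within one frame.

# Numerical and I/O choices

* Units: cm^-1 for wavenumbers, nm for lengths, W for powers, K for
  temperatures, seconds for time; conversions only at I/O boundaries.
* Stacks travel as multi-page 32-bit float TIFF plus a CSV sidecar carrying
  the axis (`page_index`, `wavenumber_cm1` or `time_s`, `pixel_size_nm`);
  axes never ride in TIFF tags, avoiding metadata dialect ambiguity. The
  codec (little-endian, uncompressed, IEEE-float samples, one strip per
  page) lives in the package because the available R TIFF bindings store
  integer-scaled samples clamped to [0, 1], which cannot round-trip
  scientific float data; interoperability is verified against an external
  reader in the tests.
* Configurations are YAML/JSON with a checked `schema_version`, rejected
  unknown keys, and mandatory explicit seeds for stochastic stages;
  pipeline reports name the md5 of the canonical config serialization so
  outputs can be traced to the exact configuration.
* Test and acceptance problem sizes — 500 events per calibrant, 10,000
  dwells per state, 141-point amide spectra, 20-seed recovery sweeps — are
  chosen to match the scale of the corresponding published analyses while
  keeping the whole suite comfortably fast on a laptop.

# Known limitations

* The forward model is scalar, quasi-static and steady-state; no vectorial
  high-NA focal fields, no Gouy-phase axial contrast, no transient heat
  transport beyond the rise-time correction.
* The denoising hook ships only a frame-averaging baseline (sqrt(n) noise
  reduction); learned denoisers plug in behind the same interface.
* Free-shape amide-I fitting is statistically fragile at realistic noise
  (see above); fraction estimates are only as good as the band library when
  line shapes deviate from it.
* Overlapping molecules within one PSF are flagged, not resolved.
* `k_on` accuracy is bounded by knowledge of the ligand concentration, and
  no mass-transport correction is applied.
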