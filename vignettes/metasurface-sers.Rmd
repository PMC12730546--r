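---
title: "Quasistatic metasurface plasmonics and correlative SERS analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quasistatic metasurface plasmonics and correlative SERS analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metasers)
```

## The physical model

A flexible metasurface (FMS) for surface-enhanced Raman scattering (SERS)
is a thin silver film deposited on a periodically modulated polycarbonate
substrate: period $L \approx 400$ nm, peak-to-valley modulation
$h \approx 80$ nm, crest thickness $d \approx 15$ nm. Under 785 nm
illumination the film supports plasmon resonances that concentrate the
optical field in the depressions of the profile — exactly where
100-nm-scale vesicles such as exosomes settle. Because the analysis is
quasistatic (structure much smaller than the wavelength), the optics reduce
to a 2-D electrostatics problem that this package solves in closed form.

The analytic route runs through an exactly solvable auxiliary system, a
hollow metal nanocylinder with inner radius $r_i$, outer radius $r_e$ and
radius ratio $\alpha = r_e/r_i$, embedded between an interior dielectric
$\varepsilon_i$ and an exterior $\varepsilon_e$, with metal permittivity
$\varepsilon_m = \varepsilon_m' + i\varepsilon_m''$ (time convention
$e^{-i\omega t}$, so passive media have $\Im\,\varepsilon \ge 0$). Every
scattered-field coefficient shares the denominator

$$\mathrm{Det} = \alpha^2(\varepsilon_e + \varepsilon_m)
(\varepsilon_i + \varepsilon_m) +
(\varepsilon_m - \varepsilon_e)(\varepsilon_i - \varepsilon_m),$$

implemented by `resonance_det()`. Resonance is the minimum of
$|\mathrm{Det}|$; neglecting loss it occurs at the critical ratio returned
by `alpha_res()`. The depth of the minimum is controlled by the metal
optical quality $Q_m = |\varepsilon_m'|/\varepsilon_m''$
(`optical_quality()`; $Q_m \approx 78$ for silver at 785 nm), with the
large-$Q_m$ estimate `det_res_estimate()` documented as an estimate — the
exact value is `resonance_det(alpha_res(...), ...)`.

An internal source at dimensionless offset $a \in (0,1)$ drives the dipole
harmonic of the cylinder. Its induced uniform field amplitude $A$ has a
closed form (`dipole_amplitude()`), and the package also reconstructs all
four potential coefficients $A, B, C, D$ by solving the boundary-matching
linear system (`solve_matching_system()`): continuity of the potential and
of the normal displacement at $r = 1$ and $r = \alpha$. The two routes are
independent — one is printed algebra, the other a numerical solve — and
their agreement to $10^{-8}$ over a parameter grid is one of the package's
standing oracle tests. Only the dipole term is implemented in closed form:
it dominates the SERS response, while the leading logarithmic (circular
field) term of the source expansion is independent of the metal
permittivity and is therefore exposed (`source_potential()`) but excluded
from enhancement maps. The printed closed form for the amplitude maximum at
resonance is typographically corrupt in the source literature; the package
exposes $|A|$ at resonance computed from the exact expressions instead and
records only the $A_{\max} \sim Q_m$ scaling.

The conformal map $z_1 = -i \log(w - a)$ carries the annulus onto a
periodically modulated film. The two film surfaces follow in closed form
(`fms_profiles()`), and the film parameters map to cylinder parameters as
$a = \tanh(\pi h/L)$, $\alpha = a + (1-a)e^{2\pi d/L}$ (`fms_geometry()`,
inverted exactly by `fms_from_cylinder()`). The map multiplies the uniform
interior intensity by $|dw/dz_1|^2 = e^{-4\pi y/L}$, giving the local
intensity enhancement $|E/E_0|^2 = |A|^2 e^{-4\pi y/L}$
(`field_intensity()`) and the SERS gain $G = (|E/E_0|^2)^2$
(`sers_factor()`). The field is therefore largest in the depressions; for
the default design the depression/crest intensity ratio is
$e^{4\pi h/L} = 12.34$. (The source literature prints this ratio with a
negative exponent while its own sign convention makes the depression field
the larger one; the package implements enhancement-in-depression and
documents the discrepancy.) The surface-averaged resonant gain is
$G \sim Q_m^4 \approx 4 \times 10^7$ for silver (`sers_average()`), and the
field at the depression bottom has the design estimate implemented in
`emax_estimate()` — about 16 in amplitude (so $\sim 257$ in intensity) at
the default parameters; both numbers are reported because the source
literature describes this loosely as a two-orders-of-magnitude enhancement.

Design helpers: `optimal_thickness()` evaluates the optimal crest thickness
$d_{\max} = (L/2\pi)(\varepsilon_e+\varepsilon_i)/((1-a)|\varepsilon_m'|)$
(16.87 nm at the defaults, consistent with the 15 nm design) and the
thinner metal at the depression bottom; `resonance_scan()` scans thickness,
maps each $d$ to $\alpha$, and brackets the $|\mathrm{Det}|$ minimum with a
dense grid plus golden-section refinement (relative tolerance $10^{-9}$,
ties toward smaller $d$). The quasistatic expressions are evaluated
regardless of $L/\lambda$; `quasistatic_validity()` prints $L/\lambda$ and
a conventional skin-depth estimate as a caveat, never as a hard gate,
because the validity condition in the source literature is ambiguous as
printed.

```{r design}
spec <- fms_geometry(L = 400, h = 80, d = 15)
spec
alpha_res(-29.8, eps_i = 1, eps_e = 2.5)
optimal_thickness(400, 80, eps_i = 1, eps_e = 2.5, eps_m_re = -29.8)$d_max
```

## The limit-of-detection pipeline

Sensitivity is calibrated with a thiol-bound reporter molecule
(4-mercaptophenylboronic acid, 4-mPBA) in a dilution series. Per spectrum
the pipeline measures a signal and a noise parameter:

* **Baseline** (`estimate_baseline()`): a Whittaker smoother (quadratic
  difference penalty, sparse solve) with iterative masking of points more
  than 2 robust standard deviations above the fit. Constants and linear
  ramps are reproduced exactly; bands are excluded from the fit by the
  masking. The default stiffness $\lambda = 10^8$ (on a 0.5–1 cm$^{-1}$
  grid) is deliberately high: a softer baseline partially absorbs weak,
  unmasked bands, which deflates the measured signal precisely near the
  detection limit. No baseline algorithm is prescribed by the measurement
  itself, so the smoother and its parameters are configuration-exposed and
  validated by property tests only.
* **Noise** (`noise_amplitude()`): the mean absolute baseline residual over
  quiet windows (600–650 and 1650–1700 cm$^{-1}$ by default), an unbiased
  estimate of $\sigma\sqrt{2/\pi}$ for Gaussian noise.
* **Signal** (`band_intensity()`): the baseline-subtracted band height at
  the nominal 1589 cm$^{-1}$ position. The height-at-centre reading is
  used rather than the window maximum because the maximum of a 30-point
  window carries a positive extreme-value bias of roughly two noise
  standard deviations when the band is weak — the same order as the
  detection criterion itself — which visibly bends the S/N–concentration
  line near the limit of detection and biases the recovered limit ~30%
  low. The window maximum and the band area remain available as options.

`series_sn()` assembles S/N per concentration. Because baseline noise is a
property of the detector, not of the analyte concentration, the default S/N
denominator is the noise amplitude pooled across the series; this keeps the
calibration line on a common scale and roughly halves the variance of the
fitted intercept (per-spectrum denominators are available with
`pool_noise = FALSE`). `fit_lod()` then fits ordinary least squares of S/N
on concentration — with an intercept by default, since the linear relation
is stated without specifying a fit through the origin; both variants are
available — and solves the fitted line for the S/N = 3 criterion. The
criterion is a named argument, not a constant. A non-positive slope is an
error ("no detection"); an intercept already above the criterion yields an
extrapolation flag and warning.

```{r lod}
series <- gen_dilution_series(seed = 1)
fit_lod(series)
```

For exosome-like spectra, `detect_peaks()` finds local maxima above
`min_snr` noise units (via prominence-gated peak search with interpolated
FWHM) and `assign_bands()` labels each peak with the unique window of the
packaged nine-row assignment table (`exosome_band_table()`: protein,
lipid, nucleic-acid and carotenoid bands between 715 and 1630 cm$^{-1}$),
or `"unassigned"` — for example, a peak at 1450 cm$^{-1}$ falls in the gap
between the 1300–1370 and 1495–1530 windows.

## What the synthetic data emulate — and what they do not

The package generates every fixture it tests against
(`gen_spectrum()`, `gen_dilution_series()`, `gen_surface_pair()`), fully
deterministic under a seed.

*Spectra* are sums of Gaussian bands on a polynomial baseline with
additive white Gaussian noise, on a 600–1700 cm$^{-1}$ grid (0.5 cm$^{-1}$
steps for the dilution series, a typical CCD sampling). The dilution
series uses the four-step set 50, 5, 0.5, 0.05 µM. (The source experiment
lists the lowest concentration inconsistently — 0.2 µM in the methods
section, 0.05 µM in the results — and the package follows the results
set.) The reporter band height is scaled so the expected measured S/N is
15 per µM, i.e. S/N = 3 at 0.2 µM. Real SERS spectra differ in ways the
generator does not model: Lorentzian/Voigt lineshapes, fluorescence
backgrounds with curvature, heteroscedastic (shot-noise) detectors, and
adsorption saturation of the S/N law at high concentration. Passing tests
therefore demonstrate the pipeline's statistical behaviour, not
instrument-level fidelity.

*Surface maps* combine a doubly periodic lattice, objects, and roughness,
pixel-for-pixel co-registered between a height (AFM) and a current (SSRM)
channel at 1024 × 1024 px and 10 nm/px (a 10 × 10 µm field). The 2-D form
of the doubly modulated surface is not specified anywhere, so the lattice
is modelled as the separable sum of the closed-form profile along both
axes, normalised to peak-to-valley $h$ — a documented stand-in.
Exosomes are spherical caps (height 0.45 × diameter by default, within the
0.3–0.6 range plausible for dried vesicles; diameters default to
80–120 nm, the mid-range of the 30–150 nm population) that also zero the
local current; silver-deposition defects zero the current without
topography; fabrication imperfections are caps without a current drop.
Roughness is smoothed Gaussian noise of 4 nm rms; current noise is 5%
multiplicative; SSRM physics is not modelled — currents are normalised to
1 and only the qualitative conductive/non-conductive contrast is
represented. No tip convolution, no drift, no registration error.

## Correlative identification

`remove_lattice()` notches the lattice out of the height map in the
Fourier domain. Because the separable lattice confines all its spectral
energy — fundamental, harmonics, and the leakage that appears whenever
$L$ does not divide the scan width — to the two frequency axes, the
default removes those axis lines entirely (equivalently: row and column
means), which also cancels any global tilt and offset; narrow per-harmonic
notches (3 bins) are available for commensurate scans. A bump loses only
$\sim 2/N$ of its energy to the notch and survives with well above 70% of
its height.

`detect_low_conductivity()` thresholds the current map at
`(1 - drop_fraction)` times the median (default: below 10% of the median —
the "significant drop" has no quantitative definition in the source, so
the default is stated, not inferred) and labels connected components.
`detect_bumps()` thresholds the lattice-free residual at `min_height`
(default 25 nm, about six times the default roughness rms) and gates the
lateral FWHM to 30–150 nm, flagging multi-peaked blobs as clusters, since
topography alone cannot distinguish one vesicle from a small aggregate
without that flag. `classify_sites()` applies the decision table:

| low conductivity | exosome-like bump | class |
|---|---|---|
| yes | yes | `exosome` |
| yes | no | `silver_defect` |
| no | yes | `imperfection` |
| no | no | `clean` (not reported) |

with SSRM–AFM matching within half a period (200 nm), reflecting
depression-centred deposition. `cross_section()` and `estimate_period()`
reproduce the morphometric analysis: per-period modulation swings along a
polyline (extrema located on a 30 nm smoothed profile and refined on the
raw one) and the dominant FFT period of the map.

```{r classify}
model <- random_surface_model(seed = 1, npix = 256, n_exosomes = 2,
                              n_defects = 1, n_imperfections = 1)
pair <- gen_surface_pair(model)
sites <- classify_sites(
  detect_low_conductivity(pair$current),
  detect_bumps(remove_lattice(pair$height, L = 400)))
score_classification(sites, pair$truth)
```

## Numerical choices and problem sizes

* Lengths are nm throughout the plasmonics core; wavenumbers (cm$^{-1}$)
  exist only in the spectra module. The conformal log uses the principal
  branch with $x_1 \in (-\pi, \pi]$ tiled periodically; profiles are
  evaluated from their closed forms, never by inverting the map
  numerically.
* Degenerate geometry: $h = 0$ and $d = 0$ are valid flat-film limits;
  $a \ge 1$ or $\alpha \le a$ are hard errors. Inputs with
  $\Im\,\varepsilon < 0$ are rejected rather than silently conjugated.
* Resonance scans: 400-point dense grid, golden-section refinement at
  relative tolerance $10^{-9}$, ties toward smaller $d$; a minimum on the
  range boundary warns.
* The test suite and the acceptance script use 20-seed dilution series
  (80 spectra of 2201 points) and ten 1024² map pairs — sizes chosen so a
  complete run is a matter of a minute or two on one core while keeping
  the Monte-Carlo error of the recovered detection limit near 5%.
* All randomness flows from explicit integer seeds; generated surfaces and
  spectra embed their seed in the written metadata.

## Known limitations

Only the dipole resonance is in closed form (no quadrupole or higher
orders, for which no closed forms are available); there is no full-wave
electromagnetic solver, no far-field spectra, no metal dispersion database
beyond the user-supplied permittivity; maps are assumed co-registered, as
produced by a combined AFM/SSRM instrument; and there is no multivariate
classification of exosome spectra by cell line or pathology — the spectral
module stops at band assignment.
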