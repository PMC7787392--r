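---
title: "Quantifying UV-C dose from photochromic indicators: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying UV-C dose from photochromic indicators: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcidose)
library(dplyr)
```

## The measurement problem

Ultraviolet-C decontamination protocols (for example N95 respirator
reprocessing) require evidence that every treated surface received at least a
minimum germicidal dose, commonly 1.0 J/cm². Electronic radiometers measure
dose accurately at one point, but they are expensive, bulky, and cannot be
draped over the curved surface of a respirator. Photochromic indicators
(PCIs) — small stickers whose color shifts with accumulated UV-C exposure —
can be placed anywhere in a treatment chamber, but out of the box they offer
only a qualitative "compare against the reference card" readout.

`pcidose` turns PCI color change into a quantitative dose measurement with a
defensible uncertainty. The pipeline is:

1. measure the CIELAB color of an exposed indicator and an unexposed
   reference (spectrocolorimeter, flatbed scanner, or camera image);
2. reduce the pair to a color-difference scalar, by default the CIEDE2000
   ΔE;
3. calibrate ΔE against known doses with a reaction-kinetics curve;
4. invert the curve for unknown samples and propagate all uncertainty
   sources into a confidence interval on the dose.

## Color metrics

All comparisons are differences between an exposed sample and an unexposed
reference measured under the same conditions; differences are far more
robust to instrument and illumination drift than absolute color.

The package implements the full CIEDE2000 formula (lightness, chroma and hue
weighting functions plus the blue-region rotation term, parametric factors
`kL = kC = kH = 1`), validated in the test suite against the ten published
sample/reference pairs to four decimal places and against an independently
coded implementation (`farver`). Companion metrics — CIELAB 1976 Euclidean
distance, RGB Euclidean distance, the signed component differences ΔL*, ΔC*,
ΔH* (CIE 1976 metric hue difference with the `a_R·b_E` vs `a_E·b_R` sign
rule), ΔR/ΔG/ΔB, and per-channel colorimetric absorbance
`−γ·log10(I/I0)` — are provided because the best-calibrating metric is
indicator-dependent.

Numerical choices worth noting:

* The ΔH* radicand is clamped at zero before the square root; rounding can
  drive it a few ulp negative for near-identical colors. The clamp preserves
  the exact decomposition `ΔL*² + ΔC*² + ΔH*² = ΔE₇₆²` to 1e-9 on random
  colors, while identical-color ΔH* may be as large as `sqrt(eps)` (≈1e-7) —
  the square root amplifies rounding, which is why the tests use a 1e-5
  band there.
* Absorbance uses base-10 logarithms (the absorbance convention) and γ = 1
  by default.
* sRGB ↔ CIELAB conversion (D65) is implemented in the package with the
  standard IEC 61966-2-1 matrices so that out-of-gamut conversions can be
  clipped *and flagged* per color; `farver` serves as the oracle in tests
  (agreement within 0.02 Lab units, attributable to matrix rounding).
* Colors carry an illuminant/observer tag (`"D65/10"` for
  spectrocolorimeter readings, `"D65/2"` for sRGB-derived values).
  Differences across tags are refused rather than silently adapted: chromatic
  adaptation is a modelling decision the user must make explicitly.

## Calibration model

Two saturating dose-response forms are supported, motivated by first- and
second-order reaction kinetics of the color-forming chemistry:

* first order: ΔE(d) = a·(1 − e^(−d/b)), asymptote `a`;
* second order: ΔE(d) = ½·a²·b·d / (1 + a·b·d), asymptote `a/2`.

Both pass through the origin and are strictly increasing for `a, b > 0`.
These are calibration functions, not mechanistic fits: because the map from
reaction-product concentration to ΔE is unknown, the fitted `a` and `b` do
not estimate chemical rate constants.

`fit_calibration()` performs unweighted nonlinear least squares
(Levenberg–Marquardt via `minpack.lm`, relative tolerance 1e-10, up to 1000
iterations). Starting values are deterministic and scale-aware: `a₀` is the
maximum observed ΔE (doubled for second order) and `b₀` comes from the dose
at half-saturation (`b₀ = d_half / ln 2` first order, `b₀ = 1/(a₀·d_half)`
second order). The parameter covariance comes from the fit Jacobian;
residual degrees of freedom are `ν = n − 2`. Model choice between the two
orders (or between readout devices) is by residual sum of squares,
`model_selection_sse()`.

The measurement noise `s_ΔE` is *not* estimated from calibration residuals
by default: it should be measured directly as the standard deviation of
replicate unexposed-indicator readings against a fixed saturated reference
(typical values: 0.273 for a mottled-coating indicator, 0.083 for a more
uniform one, in CIEDE2000 units). If no value is supplied the residual SD is
substituted with a message.

## Inverse prediction and uncertainty

Unknown doses come from the closed-form inverses
(`dose = −b·ln(1 − ΔE/a)` and `dose = ΔE/(½a²b − abΔE)`), which exist only
strictly below the asymptote. Near the asymptote the inverse and its
derivatives diverge — the indicator is saturated and carries no dose
information — so inversion refuses ΔE above 98% of the asymptote
(configurable), and estimates above 90% are flagged `near_saturation`.

The standard uncertainty is the delta method applied to the inverse, using
the analytic partial derivatives with respect to `a`, `b`, and ΔE:

u²_dose = (∂d/∂a)²·s²_a + (∂d/∂b)²·s²_b + (∂d/∂ΔE)²·s²_ΔE + 2·(∂d/∂a)(∂d/∂b)·s_ab

Confidence intervals use the Student-t quantile with the fit's ν. We report
the relative CI width (full width / dose) and the relative uncertainty (half
of it). The test suite verifies the partials against central finite
differences (1e-6 relative), the delta method against 10⁵-draw Monte-Carlo
propagation (within 5% at mid-range ΔE), and the empirical 95% CI coverage
over 500 simulated calibrations (8 doses spanning 0–250 mJ/cm², 3
replicates, noise SD 0.273 — problem sizes chosen to mirror a realistic
bench calibration while keeping the simulation study quick).

Replicate handling follows metrological convention: replicate exposures are
first equalized to a common target dose by the ratio of target to
radiometer-logged dose (a pure rescaling, so dose, CI bounds and standard
uncertainty all scale by the same factor and relative uncertainty is
unchanged); then `u_total = sqrt(u²_dose + u²_rep)` combines the propagated
and replicate components; relative doses divide by a reference location
with `u_norm = |dose_norm|·sqrt((u_meas/dose_meas)² + (u_ref/dose_ref)²)`.

## Image-based readout

Camera and scanner images extend a single-point spectrocolorimeter to
spatially resolved measurement. Inputs are converted TIFF/PNG (raw
demosaicing is out of scope); gamma-encoded files are linearized with the
sRGB transfer function on read so that all averaging happens in linear
light. Regions of interest are axis-aligned rectangles in 0-based,
half-open pixel coordinates supplied as a CSV/tibble — a file-based contract
chosen over interactive selection for reproducibility.

White balance divides each channel by the mean of the designated white
region and rescales so white maps to 0.9 per channel — the target preserves
highlight headroom; its exact value cancels out of color differences taken
within one corrected image. The correction is applied *before* region
averaging (an explicit assumption; correcting first means the averaged
values are already comparable across images). Both per-image references
(camera workflow) and shared references (scanner workflow, one unexposed
patch serving many exposed ones) are supported. Pantone-match regions are
read and stored but never analyzed.

`dose_image()` maps every pixel's ΔE against the unexposed reference through
the inverse calibration, flagging (not clipping) saturated pixels — useful
for visualizing shadowing, e.g. by marker ink or mask straps.

## Radiometer logs and lamp stability

Dose is the left-Riemann sum Σ I·Δt over the logged intervals (trapezoidal
integration is available; for 1 s sampling the difference is below one
sample's area). Lamp shutoff is detected as the first sample-to-sample drop
exceeding half the maximum recorded irradiance; analyses end two samples
earlier. The drop is referenced to the *recorded* maximum rather than a
running maximum — during early warm-up the running maximum is tiny and
measurement noise would false-trigger the detector. Warm-up is summarized
by the 10–90% rise time (linear interpolation at the crossings; `τ·ln 9`
for an exponential), long exposures by the least-squares degradation slope,
and snapshot-extrapolation error by comparing time-to-target-dose estimates
from a start window (iterations 10–20, 1-based) and an end window (last 11
iterations before shutoff).

## Optical attenuators

A filter of transmittance `T` rescales the dose axis:
`ΔE(d; filtered) = ΔE(T·d; unfiltered)`, i.e. `b → b/T` (first order) or
`b → b·T` (second order), with the covariance transformed consistently — an
exact algebraic identity verified in the tests. Dynamic-range extension is
reported two ways: the ratio of dose-scale parameters, and the
*color-matched extended limit* — the filtered dose whose predicted ΔE equals
the unfiltered prediction at a stated unfiltered limit. The color-matching
convention is used because the alternative (matching a relative-uncertainty
contour) requires the filtered fit's covariance, which published fits often
omit; when a covariance is available the uncertainty-based definition can be
computed directly with `predict_dose()` on the filtered model.

## The synthetic-fixture generator

Every input kind can be generated with known ground truth, so the entire
workflow is testable without instrument data:

* `gen_calibration_dataset()`: kinetic curve plus Gaussian ΔE noise
  truncated at zero. Defaults are the PCI1-like study conditions (first
  order, a = 47.1, b = 80.4 mJ/cm², noise SD 0.273, 8 doses spanning
  0–250 mJ/cm², triplicates).
* `gen_swatch_image()`: side-by-side exposed / unexposed / saturated /
  white patches, colors interpolated in CIELAB between a yellow unexposed
  endpoint Lab(85, 5, 60) and a pink saturated endpoint Lab(55, 45, 5) at
  reaction extent `1 − e^(−d/b)`, with per-pixel noise, optional channel
  gains (to exercise white balance) and an optional second-dose mask. The
  endpoints are fixed, arbitrary choices giving a maximum CIEDE2000 near
  the ~45–50 scale of real indicators.
* `gen_irradiance_log()`: exponential warm-up, linear degradation, noise,
  terminal shutoff.
* `gen_spatial_field()`: radial falloff with the bounding-box corners at an
  exact fraction (default 0.4) of the center dose, on a 63.5 mm grid.

All generators take an integer seed, restore the caller's RNG state, and are
byte-identical under a fixed seed.

One caveat is intrinsic: CIEDE2000 is nonlinear, so ΔE computed between
interpolated swatch colors follows the generating kinetics only
approximately. The dose-scale parameter is still recovered within a few
percent, but the fitted amplitude equals the CIEDE2000 span of the endpoint
colors rather than any `a` you feed the generator. Tests that need exact
kinetic ground truth therefore use `gen_calibration_dataset()` (exact-ΔE
mode); image tests assert end-to-end *dose* recovery (within 10%), where
the nonlinearity largely cancels because calibration and recovery share the
color path. Passing synthetic tests consequently demonstrate the numerical
machinery, not the behavior of real PCI chemistry: real coatings have
batch-to-batch color variation, temperature and humidity sensitivity, and
non-Gaussian noise that the generator does not emulate.

## Worked example

```{r example}
cal <- gen_calibration_dataset(seed = 1)
fit <- fit_calibration(cal, "first", s_delta_e = 0.273)
fit
tidy(fit)

# quantify an unknown reading
predict_dose(fit, 30)

# attenuator-extended range
ext <- range_extension(fit, filtered_model(fit, 0.05), unfiltered_limit = 200)
ext
```

## Known limitations

* Chromatic adaptation between illuminant/observer conditions is refused,
  not performed; mixed-instrument campaigns need a common reference
  condition.
* Calibration is unweighted; if ΔE variance grows with dose a weighted fit
  would be more efficient (the uncertainty propagation would carry through
  unchanged).
* The delta method is a first-order approximation; it degrades near
  saturation, which is one reason for the 98% guard band.
* Radiometer angular-response corrections are consumed as user-supplied
  per-location multipliers; deriving them requires optical modelling outside
  this package's scope.
* Raw camera files must be converted to linear TIFF/PNG upstream.
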