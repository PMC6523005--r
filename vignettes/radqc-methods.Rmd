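---
title: "Methods: attenuation metrics and perpendicular-ray geometry in radqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attenuation metrics and perpendicular-ray geometry in radqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radqc)
```

## The attenuation model

A diagnostic x-ray beam is polyenergetic. As it penetrates an absorber the
soft part of the spectrum is removed preferentially, so the effective
attenuation coefficient decreases with depth (beam hardening) and the
kerma-rate-vs-thickness curve falls more slowly than a single exponential.
`radqc` represents the beam as a small set of spectral components, each
attenuated at its own rate; transmitted kerma rate through thickness $t$ is

$$K(t) = \sum_i a_i e^{-m_i t},$$

and the fitted working model is the two-term ("second-order exponential
decay") special case

$$K(t) = a_1 e^{-m_1 t} + a_2 e^{-m_2 t},
  \qquad a_1, a_2, m_1, m_2 \ge 0 .$$

This form is exactly what a two-component spectrum produces, it nests the
monoenergetic single exponential ($m_1 = m_2$ or $a_2 = 0$), and with 11
thickness points (0–5 cm in 0.5 cm steps) its four parameters are
comfortably identifiable.

**Assumptions.** Narrow-beam geometry (scatter does not reach the
detector); a stable tube output over the measurement series (drift shows
up as repeat-to-repeat noise, not bias); absorber slabs of uniform nominal
thickness. Repeats are averaged *before* fitting; the fit is unweighted.

### Half-value layer and half-value density

The half-value layer is the thickness at which the *fitted* curve reaches
half its fitted zero-thickness value:

$$K(t_{1/2}) = \tfrac{1}{2}(a_1 + a_2).$$

Using the fitted rather than the measured $K(0)$ makes the HVL a property
of the smooth curve and insensitive to the noise in the single $t = 0$
reading; `solve_hvl(..., reference = "measured")` provides the
measured-reference alternative. The root is found by bracketed bisection to
$|\Delta t| < 10^{-9}$ cm — the objective is smooth and strictly
decreasing, so bisection is guaranteed and its cost (~60 iterations) is
negligible.

The linear attenuation coefficient is reported as $\mu = \ln 2 / t_{1/2}$
(positive; the equivalent form $\ln(0.5)/t_{1/2}$ differs only by the sign
convention absorbed into the definition).

The **half-value density** replaces thickness by cumulative areal density
(g/cm²): the averaged curve is refitted against
$t / t_{\text{article}} \times \sigma_{\text{article}}$ and solved for 50%
identically. For articles of uniform areal density this is an exact linear
reparametrization, so the refit must agree with the nominal scaling
$\mathrm{HVD} = t_{1/2} / t_{\text{article}} \times \sigma_{\text{article}}$
to within $10^{-6}$ relative; `compute_hvd()` computes both and warns on
disagreement. HVD removes the physical-density dependence of HVL, which is
what makes it comparable across filaments printed at different densities.

HVL thicknesses are computed on the *nominal* thickness basis; measured
thickness enters only through the areal density. This matches how such
specimens are used in practice (nominal slabs stepped into the beam).

### Fitting: numerical choices

`fit_double_exponential()` minimizes the residual sum of squares with
bound-constrained Levenberg–Marquardt (`minpack.lm::nls.lm`, all four
parameters bounded below by 0). The low-level LM routine is used
deliberately: on data that are exactly single-exponential the converged
solution has $m_1 = m_2$, where the model's Jacobian is singular and
`nls`-based wrappers refuse to build a model object even though the
optimum itself is perfectly well defined.

Starting values come from the log-linear single-exponential seed
($\ln K \sim t$, slope $-m_0$, intercept $\ln a_0$), with the rate split
into a fast/slow pair $(2 m_0 s,\; 0.5\, m_0 s)$ for splits
$s \in \{0.5, 1, 2\}$ and the amplitude halved; the best-of-starts solution
is kept. The reported pair is canonically ordered $m_1 \ge m_2$ so results
are reproducible. A fit is flagged `converged = FALSE` when its RMSE
exceeds 5% of the fitted zero-thickness value, and data with no measurable
decay return the degenerate $m_1 = m_2 = 0$ fit flagged non-attenuating —
downstream HVL extraction then raises an error rather than reporting a
meaningless number.

### Trends

Both summary fits are unweighted ordinary least squares (no replication
structure survives the per-voltage reduction, and no heteroscedasticity
model is claimed):

* quadratic voltage trend $y = a\,\mathrm{kV}^2 + b\,\mathrm{kV} + c$ for
  HVL (cm) or HVD (g/cm²), requiring ≥ 3 distinct voltages;
* cross-material line, specimen HVL (mm) versus the dosimeter-reported
  aluminum HVL (mm), requiring ≥ 2 distinct abscissae.

Two reproduction caveats are worth recording. First, the bundled reference
table's aluminum attenuation coefficients were evidently computed from
*unrounded* dosimeter HVLs: at 110 kV, $\ln 2 / 5.8 = 0.11951$ rounds to
0.120 while the table carries 0.119. The package reproduces 15 of 16
coefficients exactly at three significant figures and all 16 within one
unit in the last printed digit. Second, a cross-material line refitted from
the rounded table reproduces the reference slope/intercept only to within
about 2% — the reference line was fitted to unrounded measurements. Both
are properties of rounding in the inputs, not of the estimators, which are
exact on exact data (verified against closed-form normal-equation
solutions).

Only the clear specimen has per-voltage reference rows bundled; green
specimen per-voltage HVLs were never published, so green trends cannot be
recomputed and are out of scope.

## Specimen metrology

Areal density is mass over lateral area, $\sigma = m/(LW)$ (g/cm²), per
article. Summaries are mean ± 1 standard deviation with the $n-1$
denominator. Group comparisons (e.g. filament diameters from two spools)
use the Welch unequal-variance two-sided $t$ test: the groups come from
different manufacturers, so equal variances are not assumed. The degenerate
case of two identical constant samples reports $p = 1$ with a warning
instead of failing. Because the underlying raw measurements are not
published, the package makes no claim of reproducing specific $p$-values;
the test is validated against a permutation approximation instead.

## Perpendicular-ray geometry

Place the detector plane at $z = 0$ and the focal spot at
$S = (f, \mathrm{SID})$ with $f \in \mathbb{R}^2$ the *source foot* — the
perpendicular-ray location. A marker at height $z$ above detector point $x$
projects to

$$p = f + (x - f)\,\frac{\mathrm{SID}}{\mathrm{SID} - z}.$$

For a *vertically aligned* pair (same $x$, heights $z_t > z_b$), both
projections lie on the ray from $f$ through $x$'s footprint: $p_t$, $p_b$
and $f$ are exactly collinear, for any SID. That collinearity is the entire
inverse problem — the estimation is purely 2-D in the detector plane, and
marker heights never enter it (they only set how far apart the two
projections are, i.e. the leverage of each line).

Given lines $\{(p_i, d_i)\}$ through the pairs ($|d_i| = 1$, canonical
sign), two estimators are provided:

* **least squares** (default): the point minimizing
  $\sum_i \|(I - d_i d_i^\top)(x - p_i)\|^2$, solved from the $2\times 2$
  normal equations. Degenerate (all-parallel) geometry is detected via the
  reciprocal condition number ($< 10^{-10}$) and refused.
* **pairwise centroid**: every pair of lines crossing at more than
  $\theta_{\min}$ is intersected and the centroid of the intersection
  cloud returned. This mirrors the manual procedure of drawing lines on a
  workstation and marking the overlap points; it is kept for fidelity and
  comparison, with the crossing-angle guard excluding the near-parallel
  intersections that would otherwise dominate the error.

Both agree exactly on noiseless input. Under localization noise the least
squares estimate is consistently the more efficient (median error roughly
3–4× smaller in the bundled simulations at 0.3 mm noise), and its error
decreases as the pair count grows from 2 to 4.

Marker pairs whose projections coincide within $\epsilon_{\text{sep}}$
sit on the perpendicular ray itself; they are flagged on-axis and their
shared point short-circuits the estimate. Defaults
$\epsilon_{\text{sep}} = 0.05$ mm and $\theta_{\min} = 0.5°$ are
conservative (well above double-precision noise, well below any
informative configuration) and both are arguments.

The light-field center and central-ray coordinates are caller-provided
reference points — locating them (central top fiducial, collimator
crosshair) is a manual step on the image — and `deviation_report()` then
returns Euclidean distances from the estimated perpendicular ray to each.

`estimate_sid()` inverts the top-plane magnification
$m = \mathrm{SID}/(\mathrm{SID} - H)$ of the known 10 cm marker square:
$\mathrm{SID} = H m/(m-1)$. Magnifications at or below 1 (the
parallel-beam limit) are refused as non-physical.

## What the synthetic-data generator emulates — and what it does not

`simulate_transmission_experiment()` reproduces the bench protocol:
thicknesses 0–5 cm in 0.5 cm steps, voltages 50–120 kV in 10 kV steps,
three exposures per point, and polyenergetic transmission from
two-component spectra. The built-in spectra (`default_spectra()`) use equal
weights and a fast/slow coefficient ratio of 2.5, calibrated per voltage so
the ground-truth specimen HVL equals the bundled reference HVL
(20.1–27.0 mm across 50–120 kV) and likewise for the aluminum coefficients
(2.6–6.2 mm). The ratio is a modelling choice fixed once: it produces
visible beam-hardening curvature at these depths while keeping the fit
well-conditioned.

Noise is multiplicative Gaussian on the kerma rate — dosimeter readings
are positive with approximately constant *relative* error — with draws
below $\varepsilon = -0.99$ resampled so readings stay positive. The
default `noise_cv = 0.01` is a plausible repeatability figure, not a
measured one (no repeat-to-repeat variability was published), and
`kerma_at_zero = 30` mGy/min is a typical narrow-beam bench rate; both are
arguments. The master seed is split into substreams keyed by the voltage
*value* (and, for scenes, the marker index), so subsetting a protocol
never shifts the other streams, and equal seeds give bit-identical tables.

`simulate_scene()` projects the eight corner markers and the central top
fiducial through the point source by the similar-triangle formula above
and adds seeded Gaussian localization noise per coordinate. Bottom markers
default to 2 mm above the detector (a base-plate offset; the physical
tool's value is not documented, and the inverse problem never uses it).

Deliberately **not** modelled: real tube spectra (kVp waveform, anode
angle, filtration), scatter, detector energy response and blur, focal-spot
size, marker segmentation from images, and any thickness/density
variability within an article. Passing the round-trip tests therefore
demonstrates that the estimators invert the stated measurement model —
not that real bench data are free of these additional effects.

## Validation problem sizes

The test-suite and acceptance checks run, by choice, at: 1000 randomized
noiseless projection scenes (recovery to $10^{-9}$ mm, SID 800–1500 mm);
500 noisy-scene replicates at 0.3 mm localization noise for the
estimator-efficiency comparison; 200 seeded replicates of the noisy
attenuation experiment (cv 1%, 3 repeats) for the < 2% median-HVL-error
criterion; and the full 8-voltage noiseless round trip for the 0.1%
recovery bound. These sizes give comfortably stable medians and run in a
few seconds.

## Known limitations

* The double-exponential fit is a phenomenological spectrum surrogate;
  its two recovered rates should not be read as physical spectral lines.
* HVD's dual-path identity assumes articles of equal areal density;
  article-to-article variation makes the cumulative-density abscissa only
  approximately linear in nominal thickness.
* The perpendicularity estimators assume marker centroids are already
  extracted; pixel-to-mm conversion is the only imaging concern handled.
* With all marker-pair lines near-parallel (source foot far outside the
  platform footprint in one direction), the problem is ill-conditioned;
  the estimators detect and refuse this rather than extrapolating.
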