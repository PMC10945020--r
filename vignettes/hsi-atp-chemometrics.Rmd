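---
title: "Hyperspectral chemometrics for non-invasive ATP estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hyperspectral chemometrics for non-invasive ATP estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsiATP)
```

## The problem

Adenosine triphosphate (ATP) is present in all living tissue and, in
processed meat, tracks microbial load: spoilage organisms raise the ATP
pool, so ATP concentration (expressed throughout as log10 mol/L) serves
as a rapid proxy for plate counts. Bioluminescence assays measure ATP
destructively and return one number per sample. Hyperspectral imaging
(HSI) offers a non-invasive alternative: a camera records a full
visible/near-infrared reflectance spectrum at every pixel, and a
calibrated regression model turns each pixel's spectrum into an ATP
estimate, yielding a *distribution map* of spoilage over the sausage
surface rather than a single average.

`hsiATP` implements the complete analysis chain for this problem:

1. **cube** — reflectance calibration of raw hypercubes against dark and
   white references, threshold segmentation of the sausage foreground,
   partitioning of each sausage into equal-area cross-sections, mean
   spectrum extraction, and RGB reconstruction;
2. **preprocess** — the spectral pre-treatment library (absorbance, SNV,
   MSC, min-max normalisation, Savitzky-Golay smoothing, increment
   derivatives) organised as ordered chains with fit/apply semantics;
3. **chemometrics** — Kennard-Stone sample-set partitioning, PLS1
   regression, latent-variable selection by full (leave-one-out)
   cross-validation, and R²/RMSE metrics;
4. **mapping** — pixel-wise prediction and rendering of ATP maps;
5. **rsm** — the response-surface analysis of the casing-treatment
   experiment (a five-factor central composite design);
6. **synthetic_data** — a scene generator with known ground truth that
   makes every stage testable without camera data;
7. **pipeline** — `run_pipeline()`, a deterministic end-to-end driver.

## Reflectance calibration and segmentation

Raw counts are converted to relative reflectance band by band as
`R = (raw - dark) / (white - dark)`, where `dark` is a closed-lens
exposure and `white` a 100% reflectance standard. Values are *not*
clipped to [0, 1]: glossy pixels can exceed the white standard, and
clipping would bias the scatter corrections downstream. Bands where
`white == dark` cannot be calibrated and raise an error naming the band.

Foreground segmentation is a single threshold: a pixel is sausage if its
reflectance at 695 nm exceeds 0.075 (strictly). On a black background
this separates meat from support cleanly. Named wavelengths (695 nm here;
600/550/450 nm for RGB reconstruction) are resolved to the *nearest*
band, since band grids differ between instruments.

To multiply the effective sample count, each sausage is subdivided into
15 cross-sections of equal area and the mean spectrum of each section
becomes one observation; all sections of a sausage share its reference
ATP value. "Equal area" is implemented as equal pixel count (within one
pixel): pixels of each connected component are projected onto the
component's major axis (the first principal component of its pixel
coordinates, with its sign pinned so labelling is deterministic) and the
sorted projection is cut into 15 contiguous, equal-count groups. This
generalises slicing perpendicular to the long axis to bent or irregular
outlines. Components are relabelled in reading order (centroid row, then
column) so that sausage ids are spatially meaningful.

## Spectral pre-treatments

All transforms operate row-wise (one spectrum at a time), which is what
allows the identical chain to be applied later to single pixels:

* **absorbance**: `A = log10(1 / max(R, 1e-6))`. The clamp keeps the
  logarithm finite for non-positive calibrated reflectance; a clamped
  value maps to A = 6.
* **SNV**: per-spectrum centring and scaling to unit standard deviation,
  with the sample (n−1) denominator. Removes per-spectrum offsets and
  multiplicative scatter.
* **MSC**: each spectrum is regressed on a reference spectrum by OLS and
  corrected as `(x − a)/b`. The reference is the band-wise mean of the
  *calibration* spectra — the one stateful step in the library. Chains
  learn it in `chain_fit()` from calibration rows only and never refit,
  so no information leaks from prediction rows or map pixels.
* **normalisation**: per-spectrum min-max scaling to [0, 1]. (Among the
  common conventions — min-max, unit vector norm, unit area — min-max is
  used here.)
* **Savitzky-Golay smoothing**: local least-squares polynomial smoothing,
  default degree 2 over a five-band window. Edge bands are fitted on the
  truncated one-sided window rather than padded, so polynomials up to the
  filter degree are reproduced exactly at every band.
* **derivative**: the plain increment between consecutive bands, applied
  once or twice. The conventional "1st derivative" treatment is the
  *smoothed* increment, i.e. the chain `sg_smooth` then `derivative`.
  Each differencing drops one band and moves the wavelength axis to
  interval midpoints; this bookkeeping is tracked so regression vectors
  stay aligned with pixel spectra.

`standard_chains()` returns the nine-treatment sweep used by the
pipeline: raw reflectance, raw absorbance, and — on absorbance spectra —
MSC, 1st derivative, SNV, 2nd derivative, normalisation, SNV + 1st
derivative, and 1st derivative + SNV.

## Calibration models

The Kennard-Stone algorithm selects `round(2n/3)` calibration samples
deterministically: seed with the two most mutually distant spectra
(Euclidean), then repeatedly add the sample whose minimum distance to
the selected set is largest. Ties resolve to the lowest row index, so
duplicated spectra are harmless. The split runs on pre-treated spectra.
By default it operates at segment level (15 rows per sausage); because
all segments of a sausage share one reference value, this split leaks
replicate structure between sets, so `train_chain(split_level =
"sausage")` is available to move whole sausages between calibration and
prediction when generalisation to unseen samples is the question.

PLS1 regression is fitted by NIPALS and collapsed to a regression vector
and intercept, so any spectrum is predicted as `b0 + x · b` — the form
that is matrix-multiplied across unfolded pixels for maps. At full rank
it reproduces ordinary least squares. The number of latent variables is
chosen to minimise leave-one-out RMSECV over `1..min(20, n/3)` (ties to
fewer components); held-out predictions for all component counts come
from a single NIPALS fit per fold, which is exact because NIPALS models
are nested. Reported metrics follow the usual definitions: R² against
the evaluated subset's own mean, RMSE in response units, for the
calibration set (R²c, RMSEC), the Kennard-Stone prediction set (R²p,
RMSEP), and leave-one-out cross-validation (R²cv, RMSECV).

## Distribution maps

`predict_pixels()` unfolds the masked pixels into a spectra table
(row order is the image's column-major pixel order, so refolding is
exact), applies the fitted chain with its calibration-time state, applies
the regression vector, and refolds. Pixels that trip a pre-treatment
guard — a constant spectrum under SNV, a near-zero MSC slope — are
rendered as background and counted, rather than aborting the map.
`render_map()` writes the map beside the RGB reconstruction on a linear
colour scale; limits default to the map range but should be fixed (e.g.
to the calibration ATP range) when maps are compared across sausages.
Out-of-range pixels clamp to the endpoint colours.

## The casing-treatment experiment

The sausages come from a casing-modification experiment over five
factors — soy lecithin (centre 3.33, step 1.11 g/100 g), soy oil (1.875,
0.625 g/100 g), treatment duration (75, 15 min), lactic acid (292.5,
22.5 µl/15 g NaCl) and orange extract (0.28, 0.145 g) — arranged as a
2^(5−1) central composite design: 16 cube runs at coded ±1, 10 axial
runs at ±2, and 6 replicated centre runs (32 in total). `build_design()`
infers coded levels from the design structure by snapping
`(x − centre)/step` to the nearest of {−2, …, 2}; this matters because
printed run tables round the natural levels (the orange-extract +1 level
appears variously as 0.41/0.42/0.43), and a run further than 0.25 coded
units from a canonical level is rejected as a transcription error.

`fit_quadratic()` fits the full 21-term quadratic (constant, 5 linear,
5 square, 10 interaction terms) in coded units by OLS, leaving 11 error
degrees of freedom; standard errors come from σ̂²(XᵀX)⁻¹ and p-values
from t(11). Natural-unit coefficients are derived by algebraic
back-transformation and give identical predictions. `rsm_anova()`
reports sequential (type-I) sums of squares with terms entered in the
canonical order (linear, squares, interactions), each term's share of
the total SS, and adjusted SS (t²·MSE for these 1-df terms); the
residual is decomposed into pure error (the within-replicate SS of the
6 centre points, 5 df) and lack of fit (6 df), F-tested against pure
error. `surface_grid()` and `pareto_effects()` export the surfaces over
±2 coded units and the |t| ranking against the t(11, 0.975) reference.

The packaged run table (`atp_ccd()`) and published coded coefficient
table (`published_coefficients()`) let all of this be reproduced from a
fresh install; `scripts/acceptance.R` does exactly that.

## What the synthetic generator emulates — and what it does not

No public hypercubes exist for this system, so `generate_scene()`
fabricates scenes with known ground truth. It emulates the features of
the real acquisition that the analysis depends on:

* a 151-band wavelength grid, by default 350–1100 nm in 5 nm steps. The
  instrument's band count is known but its range is not; this grid is an
  assumption that contains every wavelength the analysis names (450,
  550, 600, 695 nm).
* elliptical sausages on a dark background (reflectance 0.02), separable
  at 695 nm by construction;
* a linear ATP–spectrum relationship: each sausage's reflectance is a
  convex mixture of two smooth endmember spectra (Gaussian peaks on a
  baseline, concentrated in the 350–450 and 600–750 nm regions where
  meat spectra vary most), weighted by its ATP value rescaled to [0, 1]
  over the scene's range, with higher ATP giving higher reflectance.
  The two endmembers are designed with closely matched band-wise
  standard deviation, so the per-spectrum SNV scale factor is nearly
  constant across the ATP range and the pre-treated signal stays
  approximately linear in ATP — the regime in which a linear calibration
  is the right model, as it evidently is for the real measurements;
* scatter at two scales: a per-sausage multiplicative factor (sd 0.10)
  with a per-sausage additive offset (sd 0.005) and a smooth linear
  spectral tilt (sd 0.01), representing sample-to-sample differences in
  curvature, placement and illumination that *do not* average out over
  segments — the corruption scatter-corrective pre-treatments exist to
  remove — plus per-pixel multiplicative (sd 0.04) and additive
  (sd 0.01) texture noise, and independent band noise (sd 0.005). All
  draws are truncated at 3.9 sd so the foreground/background separation
  guard at 695 nm is a hard guarantee, not a probabilistic one;
  configurations whose noise budget could cross the threshold are
  rejected outright.
* dark and white reference frames such that the calibration formula
  recovers the constructed reflectance exactly (to machine precision at
  zero noise).

A scene is fully determined by its seed, and generation restores the
caller's RNG state.

The generator deliberately does **not** model: spectral signatures of
specific myoglobin states, casing translucency, specular glare and
shadows, spatial gradients within a sausage, wavelength-dependent camera
noise, or temperature drift. Consequently, passing tests demonstrate
that the *algorithms* are correct and that the pipeline recovers known
ground truth under realistic scatter — they do not certify any
particular accuracy on real sausages, where goodness of fit is limited
by factors outside this model (the casing alone measurably degrades it).

## Numerical choices

* Absorbance clamp ε = 1e-6; SNV uses the n−1 standard deviation; the
  MSC slope guard is |b| < 1e-12.
* Kennard-Stone ties (duplicate rows) resolve to the lowest index;
  component-selection ties resolve to fewer components.
* The major-axis sign in partitioning is pinned (largest-magnitude
  loading positive) so segment labels are reproducible; projection ties
  keep image order.
* Degenerate pixels in maps become `NA`/background and are counted in
  `n_degenerate`; degenerate model fits (zero residual) flag
  non-finite standardised effects instead of ranking noise.
* NIPALS stops early if the residual covariance underflows (an exact
  fit); requesting more components than the predictor rank is an error.
* Reflectance is never clipped; only the absorbance step clamps.

## Problem sizes

The test-suite and demonstration runs use scenes of 2–4 sausages at
70×72–94 pixels for unit checks, and the default 12-sausage scene
(270×120 pixels, 151 bands, ATP spread evenly over −9.33…−4.37) for
end-to-end recovery, with the latent-variable cap at its default. The
response-surface analysis always uses the full 32-run experiment; the
simulation-recovery study refits 200 replicated experiments at response
noise sd 0.3.

## Known limitations

* The ENVI reader supports the band-sequential float32/float64 layout
  this package writes, not the full ENVI zoo (BIL/BIP, integer types).
* Leave-one-out CV is refitted per fold; for thousands of calibration
  rows a grouped CV would be preferable (and cheaper).
* The sausage-level split is the honest generalisation test; the default
  segment-level split matches the original experimental design but
  shares sausages between calibration and prediction sets.
* `pareto_effects()` assumes 1-df terms, which is always true for the
  quadratic model fitted here.
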