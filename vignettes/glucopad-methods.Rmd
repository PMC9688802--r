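---
title: "Methods: chemometric glucose quantification from paper-pad spot images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemometric glucose quantification from paper-pad spot images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Overview

`glucopad` quantifies glucose from RGB photographs of chromogenic spots
on paper-based analytical devices. The pipeline is
simulate/photograph → preprocess → segment ROI → extract 51 features →
calibrate / train SVR → predict, plus a shelf-life decay summary. This
vignette records the scientific and numerical choices behind each
stage, what the synthetic generator does and does not emulate, and the
problem sizes at which the package validates itself.

## Response convention

Image gray values are conventionally bright-high (255 = white). The
assay logic is the opposite: a darker spot means more glucose. We
therefore define the **response** channel as `255 − gray`, where `gray`
is the 0–255 luminance gray (`0.299 R + 0.587 G + 0.114 B`). Both
variants are exposed by `rgb_to_gray()`; all dose–response statements
use the response scale, so "62% decreased color intensity" is a
positive percentage for a fading pad.

## The dose–response model

The response follows `y = a ln(x) + b` with defaults `a = 36.958`,
`b = 61.367` (so 1 mM gives exactly `b`), clamped to [0, 255]. The fit
(`fit_log_calibration()`) is ordinary least squares of response on
`ln(x)`: the logarithmic form is linear in its parameters after the
ln-transform, so iterative nonlinear fitting would add nothing.
`r_squared` is `1 − SS_res/SS_tot` (defined as 0 for a flat response),
and `residual_sd` uses `n − 2` degrees of freedom.

**Limit of detection.** The logarithmic model has no constant slope in
concentration space and no finite blank response (`x → 0` diverges), so
the LOD is formed in *signal* space: decision level
`y = blank_mean + 3.3 · blank_sd`, mapped through the inverse
calibration `x = exp((y − b)/a)`. The 3.3 multiplier is the common
ICH-style convention; `compute_lod(..., k = 3)` gives the laxer
variant. In the file pipeline the blank statistics are estimated from
the undeveloped paper around the spot (pixels beyond 1.2 × the fitted
radius): the paper itself is the natural blank of a pad assay. This
convention is a deliberate, documented choice; other groups derive LODs
from replicate blank pads, and the two need not agree numerically.

The default `valid_range` is 0.5–14 mM: above ~14 mM the developed
color is no longer stable in practice, so predictions outside the range
are flagged `extrapolated` rather than suppressed.

## Synthetic image generator

No public image set accompanies this kind of assay, so the generator
(`simulate_spot()`, `simulate_dataset()`, `simulate_stability_series()`)
produces images with exactly the statistical structure the analysis
assumes, plus full ground truth (disc mask, target response):

* **Geometry.** A circular spot (default radius 60 px in a 192×192
  image, emulating a ~4 mm sample zone) on paper-colored background
  `(0.96, 0.95, 0.92)`.
* **Color ramp.** Spot pixels interpolate paper → stain, with the stain
  default `(0.35, 0.24, 0.08)` — the warm brown of the triiodide
  product. Target responses darker than the fully developed stain are
  rendered by darkening the stain toward black, emulating saturation at
  molar-range concentrations; targets brighter than the paper are a
  parameterization error naming the offending bound.
* **Exactness.** A mean-preserving radial profile (default ±6%, darker
  center) gives the spot realistic internal structure while keeping the
  pre-noise mean response over the true disc mask *exactly* equal to
  the model value — this is the anchor for every recovery test.
* **Noise.** Additive Gaussian noise on the response scale (default
  sd 4) applied achromatically to every pixel, which doubles as paper
  grain; clipped to the displayable range. Poisson shot noise is
  omitted: at 8-bit smartphone exposure it is negligible relative to
  the Gaussian term.
* **Illumination.** An optional top-to-bottom linear intensity drop
  (`illum_gradient`). The default is 0 so that ground-truth means stay
  exact; robustness tests switch it on explicitly.
* **Determinism.** One seed fans out to per-image sub-seeds via a fixed
  integer recurrence; identical seed + parameters ⇒ bit-identical
  images and byte-identical manifests (paths in the CSV are relative to
  it for that reason). Images are written as lossless 8-bit PNG.

What the generator does **not** emulate: camera optics, white-balance
and flash variation, JPEG artifacts, perspective distortion,
coffee-ring chemistry, multi-phone variability. Passing recovery tests
therefore demonstrates correctness of the *analysis*, not robustness to
every field condition.

The default simulated study covers 0.5–20 mM in 9 levels (the
physiological range) plus 0.1–0.5 M in 5 levels (excess-intake range),
3 replicates each — 42 images. Three replicates is an assumption chosen
as the minimal standard design for chemistry calibrations.

## Preprocessing and segmentation

`preprocess()` center-crops to the target aspect ratio, resizes
(default 256×256; source images rarely share one size) and applies a
per-channel median filter (default 3 px) — a conventional choice for
impulsive sensor noise that preserves the spot edge. `segment_spot()`
scores each pixel by Euclidean RGB distance to the modal background
color (median of the border frame), thresholds with Otsu, cleans with
morphological opening (disc brush, 5 px), keeps the largest connected
component, and summarizes it as a disc (centroid +
equivalent-area radius). The chromatic criterion — distance to the
*estimated* background rather than an absolute level — is what makes
segmentation tolerant to ±10% global brightness changes. The returned
mask is the disc shrunk to `shrink_factor = 0.8` of its radius, keeping
analysis clear of rim and coffee-ring artifacts.

A consequence worth knowing: because the simulated spot is slightly
darker at its center, the shrunken ROI reads ~2% above the full-disc
target, so image-derived calibration slopes sit ~2% above the
generating coefficient. Ratio quantities (e.g. percent decay) are
unaffected. Coordinates throughout are 1-based `(row, col)`, R's native
matrix convention.

## Color spaces

Fifteen chromatic channels: R, G, B; H (degrees in [0, 360), achromatic
pixels assigned hue 0), S, V; CIELAB L\*, a\*, b\* and XYZ under sRGB
primaries with D65 white (no RGB profile information survives in a
phone JPEG, so sRGB is the only defensible assumption); and the NTSC
triplet Yn, I, Q. The YIQ matrix is pinned to the FCC coefficients
rounded to four decimals:

```
Yn = 0.299 R + 0.587 G + 0.114 B
I  = 0.5959 R − 0.2746 G − 0.3213 B
Q  = 0.2115 R − 0.5229 G + 0.3114 B
```

Both chroma rows sum to zero, so the attainable extrema over the RGB
cube are exactly ±0.5959 (I, at pure red/cyan) and ±0.5229 (Q, at
magenta/green) — a corner-point property the tests pin down exactly.

## Feature schema

45 moment features (mean, skewness `m₃/m₂^1.5`, kurtosis `m₄/m₂²`
non-excess, population moments) in channel-major order over the 15
channels, then six GLCM metrics on the standard gray channel:
contrast, correlation, energy, homogeneity, entropy (base 2) and mean
unquantized gray intensity — 51 features total. The counts 45 and 51
jointly force this 15 × 3 + 6 reading; the gray channel contributes
texture only, since its moments are linear combinations of the RGB
moments. Degenerate rules: a numerically constant sample (m₂ < 10⁻¹²)
has skewness 0 and kurtosis 3 (the Gaussian reference value);
a single-level GLCM has correlation 1 and entropy 0 with `0·log 0 = 0`.

GLCM defaults: 8 gray levels by uniform binning of [0, 255], single
horizontal offset (0, 1), symmetric accumulation, pairs counted only
when both pixels are inside the ROI mask — the most common defaults of
texture toolboxes, all configurable. Both the matrix and all six
metrics are verified against brute-force pair enumeration.

## Concentration regression

The predictor (`train_predictor()`) is ε-SVR on the standardized
features with target `log₁₀(x)`, so one model spans both the millimolar
and molar range; a radial kernel is the default. Data handling rules:

* standardization statistics come from the training split only;
* replicate groups never straddle the train/test split (default 70/30
  by group, seeded) nor cross-validation folds — images of the same
  physical replicate are not independent;
* hyperparameters by grouped-CV grid search over
  C ∈ {0.1, 1, 10, 100}, ε ∈ {0.01, 0.1}, γ ∈ (1/51)·{0.5, 1, 2};
* reported `r_squared` is computed on the held-out split;
* predictions are matched to the schema *by name*, so column order is
  irrelevant, and flagged `extrapolated` outside the training range.

An SVR (not a classifier) is used because the quantity of interest is
continuous; coarse range triage (mM vs M) falls out of the continuous
prediction at no extra cost. Above the response clamp the M-range
levels become nearly indistinguishable in color, which bounds the
achievable fit there — visible as compressed high-range predictions.

## Stability analysis

`simulate_stability_series()` scales the day-0 target response by a
linear monotone decay reaching `1 − decay_fraction_at_end` on the final
day; `percent_intensity_change()` reports `100·(1 − last/first)` on the
response scale (positive = fading). Real pads have shown non-monotone
day-to-day behavior; the simulator deliberately uses the simplest
monotone ramp because no mechanistic decay model is established, and
the analysis end only ever consumes per-day means. Storage conditions
are a grouping label, not a tested factor.

## Problem sizes and runtime choices

The self-validation scales were chosen to keep the full suite
comfortably interactive: oracle equivalence on 100 random 8×8 images
for Ng ∈ {2, 4, 8}; calibration unbiasedness over 200 noise
realizations; the end-to-end scenario at 42 images of 192² pixels with
20 re-imaged unknowns; unit scenes at 96². All randomness flows through
explicit seeds (`withr::with_seed`), so every documented number is
reproducible bit-for-bit.

## Known limitations

* No color-card or cross-device normalization: models transfer across
  phones only as far as their color pipelines agree.
* Single-spot images only; no plate layouts or perspective correction.
* The LOD depends on the documented blank convention; compare across
  studies only with matching conventions.
* The SVR grid is deliberately small; very noisy or much larger
  datasets may warrant a wider search.
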