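---
title: "Methods: image-based IDC scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based IDC scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
conventions behind `idcscore`, and what the synthetic-data tests do and
do not demonstrate.

## Problem and assumptions

Iron deficiency chlorosis (IDC) severity in soybean is rated on a 1-9
ordinal scale at the V3-V4 stage, when symptoms peak. The package scores
a plot from a single overhead RGB image under these assumptions:

* the plot has two crop rows, roughly parallel to the image X axis and
  roughly centred vertically, so cutting the image in half separates the
  rows;
* images are taken under consistent illumination with fixed exposure, so
  hue (not brightness) carries the plant/soil and health signal;
* soil hue lies below the plant window, canopy hue within it, whatever
  the stress level — chlorosis moves hue from green (~120°) toward
  orange (~40°) but not out of the 40-170° range;
* weeds are green objects *off* the crop rows; in-row weeds are not
  distinguishable by this algorithm and are not modelled.

## Segmentation

Hue is computed with the standard RGB→HSV conversion and expressed in
degrees on [0, 360). Two conventions matter:

* **Zero-chroma pixels** (gray, black, white) have undefined hue and are
  always non-plant.
* **Boundary exactness.** Hues of 8-bit pixels are rationals with
  denominator at most 255²; distinct values are ≥ 60/255² ≈ 9·10⁻⁴
  degrees apart. The conversion output is snapped to nanodegrees so that
  a pixel whose exact hue is 40° cannot fall on the wrong side of the
  inclusive window edge through floating-point round-off.

The segmentation window [40°, 170°] is closed on both ends; both edges
are configurable (`hue_lo_deg`, `hue_hi_deg`). Opening uses a disk of
radius 2 px (`open_radius_px`), about 1.8 mm at the nominal 0.9 mm/px:
larger than sensor speckle, smaller than a leaflet. Out-of-image pixels
count as foreground during erosion and background during dilation
(MATLAB's convention), so a canopy touching the image border is not
eroded from outside; with this convention opening remains idempotent
and a subset of its input, which the test suite asserts.

## Crop lines and weed exclusion

Each half-image is divided into five equal-width sections (`n_sections`;
remainder columns join the last section) to tolerate slightly rotated
rows. In each section the crop line is the Y maximizing the plant-pixel
column sum. Ties — typically full-cover columns — are resolved by
averaging the first and last maximizing Y and rounding half-up. A
section with no plant pixels at all (possible only in degenerate or
synthetic imagery) falls back to the band centre with a warning.

The line mask is 5 px thick (`line_thickness_px`; "thin" relative to a
~40 px canopy, thick enough to tolerate ±2 px localization error).
Connectivity is 8 by default (`connectivity`) so diagonally touching
leaflets stay connected; components are computed on the *full* image so
a plant spanning the half-cut is kept whole. All pixel coordinates are
1-based, row-major, y increasing downward, matching R's matrix indexing.

## Colour features

The printed class edges in common use (41-50, 51-60, 61-80, 81-140,
140-170) leave one-degree gaps, overlap at 140° and start at 41° while
segmentation starts at 40°. The package reconciles them to the
contiguous half-open partition

> OY [40, 51), Y [51, 61), YG [61, 81), G [81, 141), GC [141, 170]

so that every segmented pixel belongs to exactly one class and the five
fractions sum to 1 exactly — the identity the ratio features rely on.
The edges are configurable (`bin_edges`).

The default model feature set is {PPCF, Ratio_G, Ratio_YG, Ratio_Y,
Ratio_OY}. Ratio_GC is extracted and reported but excluded from
modelling because it is insensitive to IDC; PPC duplicates PPCF up to a
constant factor (the image area) and can be added with `include_ppc`.

## Scoring models

**LDA** is Gaussian linear discriminant analysis with per-class means,
pooled within-class covariance and empirical priors, implemented
directly so a near-singular covariance can be ridge-regularized
(λ = 10⁻⁶·trace/p added to the diagonal, with a warning) instead of
aborting — small score classes with nearly constant features must not
crash a batch run. Predictions are the arg-max posterior over the
classes present in training.

**SVM** treats the ordinal score as numeric and fits ε-insensitive
support-vector regression with an RBF kernel (`e1071`), because the two
tuned hyperparameters — ε of the insensitive loss and cost — and the
RMSE selection criterion are regression concepts; the continuous output
respects score ordering and is integerized by rounding half-up and
clipping to [1, 9]. The grid search covers cost ∈ 2^(-1..7) and
ε ∈ {0.05, 0.1, 0.2, 0.4, 0.8}; RMSE is pooled over seeded 10-fold CV
with folds stratified by score (a shuffled `rep_len` within each class,
which degrades gracefully to random assignment for classes smaller than
the fold count). RMSE ties break toward smaller cost, then smaller ε.
The RBF width γ is fixed at 1/p (p = number of features) and
configurable; features are standardized with training-set statistics.

Train/test splitting is a seeded random half/half partition; for odd n
the extra row goes to training.

**Accuracy I** is the exact-match rate of the 9×9 confusion matrix
(computer score in rows, reference in columns); **Accuracy II** also
accepts one-point-off predictions, reflecting the coarser 5-point scale
in common use. Accuracy II ≥ Accuracy I for every matrix.

## Synthetic scenes: what they emulate

`generateScene` renders, at a default 192 × 288 px (a 1/8-scale plot
image; all geometry parameters are in pixels and scale with it):

* two canopy rows at 28% and 72% of the image height, built from random
  disks (radius 6-14 px) centred on the row line with ±1 px planting
  wobble, laid down until every fifth of the row reaches the target
  column-cover fraction (default 0.5) — emulating a continuous planted
  row;
* per-pixel canopy hues drawn from a severity mixture over the five
  classes, interpolated linearly from (OY, Y, YG, G, GC) =
  (0, .02, .05, .88, .05) at severity 1 to (.55, .25, .12, .05, .03) at
  severity 9 — green-dominant when healthy, orange-dominant when
  severe, Green-Cyan always minor. Hues are drawn 1° inside each class
  so 8-bit RGB quantization cannot move a pixel across a class edge,
  keeping the realized class proportions exactly recoverable;
* off-row green weeds (hue 95-135°), at least 25 px from either row
  line and separated from the canopy by ≥ 2 px so they are
  8-disconnected from it;
* soil with hue 10-35°, below the segmentation window;
* isolated single-pixel salt noise of in-window hue, spaced ≥ 3 px
  apart, which the opening removes.

`generateFeatureDataset` skips rendering and draws features directly
from severity response curves (`idcscore:::severityCurves`): PPCF falls
linearly 0.36 → 0.04; Ratio_G falls 0.88 → 0.08; Ratio_YG rises to
score 4 then flattens; Ratio_Y responds most between scores 3 and 6 and
saturates near 0.30; Ratio_OY climbs steeply at high severity; Ratio_GC
stays at 0.03-0.05. Gaussian noise (default sd 0.03, truncated at 0) is
added per feature and the ratios renormalized to sum to 1. The office
score is the field score plus symmetric integer noise (60% exact
agreement, 35% off by one, 5% off by two), clipped to 1-9.

**What passing tests show — and do not show.** The synthetic scenes
verify the *mechanics*: segmentation recovers the canopy pixel-exactly,
weeds disconnected from the rows are always removed, realized hue-class
proportions are recovered within counting error, and on curve-generated
features both models beat 11.1% chance accuracy by a wide margin. They
do not emulate illumination drift, shadows, specular soil, in-row
weeds, overlapping rows, or rater disagreement structure, so accuracies
on synthetic features exceed what field imagery yields; field-accuracy
claims rest on the published benchmark matrices shipped under
`inst/extdata/`, not on the simulation.

## Numerical and degenerate cases

* Rounding is always half-up (`floor(x + 0.5)`), never banker's.
* An empty plant mask yields PPC = PPCF = 0 and all ratios 0 (their sum
  is not 1 in this single degenerate case).
* An empty crop-line section warns and falls back to the band centre.
* A single score class aborts LDA training; a constant target aborts
  SVM training. Both are data errors, not pipeline states.
* All randomness (scene placement, noise, splits, folds) flows through
  explicit seeds; runs are bit-reproducible and the global RNG state of
  the caller is never disturbed.

## Problem sizes used by the test suite

Oracle-equivalence tests run 100 random instances per operation at
12×12 to 24×30 px; conservation and efficacy checks use 10 and 50
full scenes at the default 192 × 288 px; model-recovery tests use a
1,500-plot feature dataset split half/half, with the full default SVM
grid. These sizes keep the suite comfortably fast while leaving every
code path exercised at realistic geometry ratios.

## Known limitations

* Crop rows must be near-horizontal; the five-section piecewise
  approximation handles mild rotation only.
* Plants fully detached from their row are deliberately discarded by
  the connectivity rule, as are plots whose canopy never touches the
  detected line (none arise under the generator's defaults).
* No colour calibration: the hue window assumes stable exposure. A
  reference panel and per-image calibration would be needed for mixed
  lighting.
* The models are trained per dataset; no cross-site transfer is
  attempted or claimed.
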