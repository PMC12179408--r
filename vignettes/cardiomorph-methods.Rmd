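---
title: "Morphometric profiling of isolated cardiomyocytes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric profiling of isolated cardiomyocytes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiomorph)
```

## The problem

Healthy isolated adult cardiomyocytes are elongated, rod-shaped,
striated cells; hypertrophic remodeling (angiotensin II, isoproterenol,
aging) changes their surface, width, length, aspect ratio and volume.
Quantifying those changes from high-content micrographs requires (i)
segmenting thousands of cells, (ii) measuring them reproducibly in
physical units, (iii) discarding touching/overlaying or abnormally
shaped objects that would bias group statistics, and (iv) aggregating
per-group summaries with appropriate tests. `cardiomorph` implements
that workflow end to end, together with two satellite measurements
(sarcomere striation period, gravity-decantation timing) and a seeded
synthetic image generator that provides ground truth for every stage.

## The synthetic generator as the reference experiment

No real acquisitions ship with the package, so every claim the test
suite makes is anchored to the generator in `render_scene()` /
`render_stack()`:

* **Intact rods** are capsules (stadium shapes): a rectangle of length
  $L - W$ capped by two half-discs of diameter $W$. The capsule has
  closed-form area $W(L-W) + \pi W^2/4$ and perimeter $2(L-W) + \pi W$,
  which the descriptor tests use as oracles. Striation is a
  multiplicative modulation $(1 + a\cos(2\pi u/s))/(1+a)$ along the
  axis coordinate $u$, with amplitude $a = 0.4$ by default and $s$ the
  sarcomere period.
* **Touching pairs** are two overlapping capsules (2–8 px overlap,
  8–30° relative angle) sharing one ground-truth label: the workflow
  deliberately does not split them by watershed; they are routed to the
  classifier as disqualified objects.
* **Rounded cells** are discs, **fragments** small capsules whose area
  is well below a single cell.
* Group geometry is drawn from truncated normals whose means and SDs
  are the reference group table (`group_reference_table()`): e.g.
  control length 139.42 ± 33.06 µm, width 28.78 ± 7.93 µm, sarcomere
  period 1.801 ± 0.034 µm, volume 35368.88 ± 19283.4 µm³. Width is
  truncated at 5 µm and length at the drawn width (both far tails);
  the volume draw is truncated symmetrically at ±1.8 SD so that the
  group mean is preserved exactly while non-physical lower-tail
  volumes are excluded.
* Class composition is allocated by the largest-remainder rule, so a
  97/2/1 mix of 100 cells is exactly 97/2/1 — tests on composition are
  not flaky. A multinomial mode exists behind the `multinomial` flag.
* The default field is 1024×1024 px at 0.65 µm/px — a desk-scale
  stand-in for the source acquisitions ("50 to 100 fields of view at a
  resolution of 2024 × 2024 pixels"; that figure is quoted verbatim
  and is plausibly a typo for 2048, which we do not resolve).
* Rendering is bit-reproducible for a fixed (spec list, seed).

What the generator does **not** emulate: optics (no PSF, no
out-of-focus light), multi-channel staining, intensity texture inside
cells beyond the striation term, debris gradients, or uneven
illumination. Passing tests therefore demonstrate correctness of the
measurement pipeline, not robustness to every real-world imaging
artifact.

## Segmentation

`segment()` reproduces an analyze-particles stage: global threshold
(Otsu by default, a fixed threshold as the alternative), optional hole
filling (so solidity reflects the outline), 8-connected labeling, a
physical size gate (default 500–15000 µm², bracketing isolated
cardiomyocyte surfaces at ±3 SD), and optional border exclusion. The
original macro's exact parameters are not recoverable from the source
material, so all of them are explicit arguments. Touching cells are
*not* split — that is the classifier's job.

## Shape descriptors

`measure_particle()` computes, per particle and in micrometres:

* **area** — pixel count × pixel area;
* **perimeter** — length of the outer contour polygon. The raw
  marching-squares contour follows the pixel staircase and inflates
  smooth perimeters by 5–10%, so the perimeter estimator traces the
  contour on a 2× replicated mask (quarter-pixel corner chamfer) and
  simplifies it with Douglas–Peucker (tolerance 0.9 px): digital
  staircases collapse to straight segments while true corners are
  preserved. On a rasterized disc of radius 35 px this gives
  circularity 0.97, on a 40-px square 0.795 (ideal π/4 ≈ 0.785);
* **circularity** — $4\pi A/P^2$, clipped at 1;
* **aspect ratio / roundness** — from the area-preserving
  moment-equivalent ellipse (second central moments with the 1/12
  per-pixel term; axes rescaled so the ellipse area equals the particle
  area). Roundness is $4A/(\pi\,\text{major}^2)$;
* **solidity** — area over convex-hull area of the contour;
* **length / width** — maximum and minimum Feret (caliper) diameters
  from rotating calipers on the convex hull, minus a half-pixel
  rasterization bias (the mid-crack contour rides slightly outside the
  true boundary). Length/width are calipers rather than ellipse axes
  because the reference group table is only consistent with caliper
  lengths alongside an ellipse-based aspect ratio (137.81/28.53 = 4.83
  while the printed aspect ratio is 5.18);
* **scaled perimeter-to-area ratio** — $P/\sqrt{A}$, the only
  dimensionless scaling consistent with standard-scaled features (its
  exact original definition is not published; this choice is a design
  decision);
* a degenerate one-pixel-wide particle has its minor axis floored at
  one pixel.

Property tests assert scale equivariance (areas ×4, lengths ×2 under
pixel-size doubling), exact pixel-size invariance of the dimensionless
features, rotation invariance within 3%, and agreement of the caliper
implementation with an exhaustive pairwise/angle-sweep oracle.

## Qualification classifier

The eight features (area, perimeter, circularity, aspect ratio,
roundness, solidity, AR × solidity, scaled perimeter/area) are
z-scored with training-split statistics and fed to an L2-regularized
logistic regression (unit regularization strength, i.e. ridge penalty
1/n per observation; deterministic coordinate-descent solver with
convergence threshold 1e-12). The split is stratified by label and
seeded; held-out accuracy, precision, recall and F1 are stored in the
model. The decision threshold defaults to 0.5 and is configurable.
Models persist as plain JSON (feature order, scaler statistics,
weights, metadata) so they can be audited and reloaded anywhere.

The shipped benchmark labels come from synthetic ground truth
(intact rod → 1, everything else → 0); the original visually verified
1000-cell training set is not deposited, so published headline figures
(~94% accuracy/precision/recall) are *echoed* by a property — ≥ 0.90 on
a 70/30 synthetic benchmark of 1000 cells — not reproduced. On that
benchmark the model separates classes essentially perfectly, which is
expected: the synthetic classes are cleaner than visually ambiguous
real cells.

Only rows with `qualified == 1` enter group statistics; this is the
single gate between measurement and reporting.

## Sarcomere period

`axial_profile()` averages intensity across a 5 µm band perpendicular
to the cell's Feret axis, sampling every quarter pixel along it (a
1.8 µm period is under 3 px at 0.65 µm/px; coarser sampling starves
the peak interpolation). `measure_period()` detrends with a moving
average (window 3× the longest physiological period, removing the
capsule envelope), computes the unbiased autocorrelation, picks the
first prominent peak in the physiological 1.0–3.0 µm gate, and refines
it by harmonic regression — the autocorrelation maxima near $kT_0$,
$k \le 5$, each refined by a 3-point parabola, are regressed through
the origin. Averaging across harmonics cancels the interpolation
ripple that biases single-peak refinement by up to 2% at axis-aligned
orientations; recovered periods are accurate to ~0.1% on clean rods
and to < 0.02 µm mean absolute error at noise SD 0.1. A periodogram
estimator (`method = "spectrum"`) serves as an independent
cross-check. Out-of-gate or low-confidence estimates yield an invalid
record, never a silent number.

## 3D volumes

`measure_volumes()` thresholds a z-stack, labels 26-connected
components (6-connectivity available), removes objects below a minimum
volume and reports voxel_count × voxel volume — exactly, with no
meshing — plus bounding boxes and a stack-boundary flag. Synthetic
stacks render cells as elliptic cylinders; when a spec carries a target
volume, the cell depth is solved from $V = \frac{\pi}{4} W D L$, so
population volume statistics follow the reference table directly while
remaining geometrically consistent. Voxel-count recovery of the
analytic volume is within ~1% at (0.5, 0.5, 1.0) µm voxels.

## Decantation kinetics

Gravity decantation is modeled as "plateau followed by one-phase
decay": $Y(X) = Y_0$ for $X < X_0$ and
$Y(X) = \text{Plateau} + (Y_0 - \text{Plateau})e^{-k(X - X_0)}$ beyond.
`fit_decay()` fits all four parameters by Levenberg–Marquardt from a
deterministic multi-start grid (bounds $X_0 \ge 0$, $k > 0$); a
fixed-$X_0$ mode exists for sparse series. The minimal decantation time
inverts the curve at a band around the plateau:
$X_t = X_0 - \frac{1}{k}\ln\frac{Y_t - \text{Plateau}}{Y_0 - \text{Plateau}}$.
"Within a 0.5% range of the plateau" is ambiguous — relative to the
decay span or to the plateau magnitude — so the span convention
($Y_t = \text{Plateau} + 0.005\,(Y_0 - \text{Plateau})$, which stays
well-defined as the plateau approaches zero and reduces to
$X_t = X_0 + \ln(200)/k$) is the default, with the literal
plateau-relative reading behind a flag. The published 24.36 min
example cannot be reproduced because the underlying absorbance series
and fitted parameters are unpublished; it is documented as motivation
only.

## Group reporting

`summarize_groups()` reports n/mean/SD/SEM per group and feature over
qualified cells; `percent_change()` is $100(\bar{x}_g -
\bar{x}_c)/\bar{x}_c$ on group means — the only convention that
reproduces all published deltas from the reference table.
`compare_groups()` delegates to the standard published tests
(Kruskal–Wallis + Dunn versus control with Bonferroni adjustment,
one-way ANOVA + Tukey HSD, Mann–Whitney U, Fisher's exact); Dunn's
test is implemented here (tie-corrected mean-rank z statistics)
because no installed package provides it. Sarcomere summaries carry
both SD and SEM, since published per-group dispersions appear in both
forms.

## Problem sizes and statistical power

The test suite runs the full pipeline at two scales chosen by the
package: a small 4×30-cell run (twice) to assert byte-identical
determinism, and a 4×1200-cell run (plus 60 volume stacks per group)
for the hypertrophy sign pattern. At 1200 cells per group the standard
error of a percent-change of means is ≈1.4 points for aspect ratio
(CV ≈ 0.33), so the weakest expected effect (isoproterenol aspect
ratio, −2.5%) sits near 1.9 SE — adequate for a seeded check, though
it remains the least-powered assertion, just as it is the smallest
effect in the original data (which used ~4000 cells per group). All
other asserted effects exceed 3 SE at these sizes. The acceptance
script uses 4×300 cells and 80 stacks per group; its pipeline deltas
are stochastic recoveries at that stated n, while its reference-table
percent changes are exact.

## Known limitations

* Segmentation is global-threshold only; dim or overlapping-intensity
  cells in real images may need local thresholding that is out of
  scope here.
* The classifier benchmark is synthetic; transferring the model to real
  measurements requires retraining on visually verified labels.
* Perimeter (hence circularity) of rasterized shapes carries an
  estimator-dependent bias of a few percent at small sizes; the
  chosen contour estimator keeps it within the documented bands for
  discs, squares and capsules, but very small particles (< ~15 px
  across) are less accurate.
* 3D rendering has no optical anisotropy; real confocal stacks blur
  along z, which voxel counting does not correct for.
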