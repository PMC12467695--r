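---
title: "Measuring the Graf alpha-angle: models, parameters, and numerical choices"
author: "GrafAngle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the Graf alpha-angle: models, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GrafAngle)
```

## The measurement model

In the Graf standard plane the infant hip presents two bright, nearly
linear bone-surface echoes: the iliac outer margin, held close to vertical
by correct probe positioning, and the bony acetabular roof, which leaves
the margin at the bony rim (osseous beak) and descends medially. The
α-angle is the angle between the *baseline* — the line along the iliac
outer margin, drawn through the rim — and the bony roof line. The package
measures it per frame in seven steps (median preprocessing, per-row ridge
maxima, intensity screening, iliac-line fit, baseline construction, roof
fit, angle computation); `measureAlpha()` orchestrates them and keeps
every intermediate line model in the result for audit.

Everything rests on one physical assumption: **bone surfaces are intensity
ridges**. The pipeline never segments anatomy; it extracts strict local
maxima along scanlines and trusts geometry (screening, region
restrictions, robust fits) to sort iliac margin from roof from noise. The
scanline direction is across rows (one scan per image row) because the
iliac margin is near-vertical in this orientation and crosses each row
exactly once; the roof, at α ≈ 55–80° from the vertical, still crosses
every row it spans.

One definitional point: α is taken between the baseline and the *bony
roof* line through the bony rim. A line to the tip of the labrum defines
Graf's β-angle, a different measurement that this package deliberately
excludes; descriptions that mix the two are treated as referring to the
bony-roof definition.

### Line representation and angle conventions

A line is stored as `LineModel(theta, offset)`: direction
`d(theta) = (cos theta, sin theta)` in (row, col) coordinates, theta in
[0°, 180°) measured from the image column (vertical) axis, positive
clockwise, and `offset` the signed perpendicular distance from the origin.
Coordinates are 1-based (row, col), the native R convention, with the
origin at the top-left. Two derived quantities:

* `angleBetween()` folds the inter-line separation into [0°, 90°]. Graf's
  α opens caudally from the baseline toward the roof and cannot exceed a
  right angle for meaningful geometry, so the fold resolves the inherent
  two-branch ambiguity of undirected lines.
* `iliacInclination()` folds theta into [−90°, 90°): 0 for a perfectly
  vertical margin, positive clockwise; theta = 175° reads as −5°.

### Why total least squares

The iliac margin is near-vertical, so ordinary regression of row on
column (or vice versa) degenerates exactly in the common case.
`fitLineTLS()` minimizes perpendicular distances via the principal
eigenvector of the 2×2 coordinate covariance; it has no preferred axis
and handles exactly vertical point sets without special-casing. The
static path seeds the fit with a Hough transform (`houghFit()`, default
1° × 1 px bins) and refines by TLS on the inliers within 2 bin widths;
accumulator ties break deterministically toward the smallest theta, then
the smallest offset. Hough ρ values are binned relative to the point-set
centroid rather than the image origin, which makes bin assignment — and
hence the selected inlier set — exactly invariant under integer image
translations; offsets are still reported in image coordinates.

### Peak screening

Screening keeps candidate peaks with intensity ≥ mean + *k*·σ of the
candidate population (*k* = 2 by default). That statistic alone fails on
clean frames: when nearly every candidate sits on a ridge, mean + 2σ lands
above the maximum and rejects everything. When the source frame is
available the threshold is therefore capped at
`median(frame) + 0.4 · (max peak − median(frame))` — any peak well
separated from the background floor survives. Both rules scale linearly
with intensity, so screening is invariant under global intensity scaling.
A second rule removes isolated bright speckle survivors: retained points
must belong to a spatial chain (single-linkage components, 7 px linking
distance) of at least 5 points. Seven pixels, not five, because the
median-filter plateaus quantize per-row roof peaks onto jumps of up to
~6 px between adjacent rows at steep roof angles; a 5 px linkage
fragments the roof chain.

### Sub-pixel refinement and the rim anchor

Integer peak positions limit line accuracy to the rasterization grid, so
before fitting, each support point's column is refined by a quadratic fit
through its 3-pixel neighborhood (clamped to ±0.5 px, skipped on flat
plateaus where the curvature is zero).

The baseline must pass through the rim, but the detected rim anchor is a
box center quantized to the detection grid and can sit 1–3 px lateral of
the margin. Since the rim lies *on* the iliac margin by definition, the
anchor is projected onto the fitted iliac line before
`constructBaseline()` is applied; the baseline then coincides with the
fitted margin. Without the projection, margin points can leak past the
roof region's baseline-exclusion band (2.5 px) and corrupt the roof fit.

## The landmark detector

The reference detector is classical and deterministic, standing in for a
learned bounding-box model behind the same contract (at most one labelled
box per landmark, rim first, confidence in [0, 1], empty output — never a
fabricated box — when contrast is insufficient). It finds the dominant
near-vertical chain by Hough transform (the iliac margin), takes its
caudal terminus as the rim (ties broken toward the greater row), fits the
remaining off-margin chain (the roof), and takes the roof inlier farthest
from the iliac line as the lower limb of the ilium. Boxes are fixed-size
24×24 px centered on the keypoint — real detectors learn box extents, but
the downstream geometry only uses box centers and spans. Confidence is the
normalized ridge-to-background contrast
`(median ridge intensity − frame median) / (255 − frame median)`, floored
at 0.1 below which no detection is emitted.

## The synthetic phantom

`makeScene()` builds the geometry analytically — the stored α is exact to
machine precision, and rasterization happens only at render time. The
default layout on a 256×256 canvas (0.1 mm/px, recorded in metadata):
rim at (150, 110); iliac margin 110 px long ending caudally at the rim;
roof segment 70 px long leaving the rim at exactly α to the margin;
ridges rendered 2 px thick. The lower limb of the ilium is placed at the
roof's medial terminus — Graf's roof line runs from the lower limb
through the rim — which also makes the roof-fit region (the two landmark
boxes dilated by 10 px) span the roof. The physical phantom such scenes
emulate publishes only its reference angle, so every other geometric and
acoustic parameter is an explicit package choice, fixed here and recorded
in the scene object.

`renderFrame()` applies, in order: multiplicative unit-mean Rayleigh-like
speckle (blend weight `speckleScale`), Gaussian point-spread blur
(`blurSigma`, px), and a column-wise acoustic shadow (fraction
`shadowAttenuation` removed starting 3 px below the deepest bone surface
of each column — deep to the bone, where real acoustic shadow falls), then
quantizes to 8 bits. Defaults (speckle 0.2, blur 1.0 px, shadow 0.3,
background 20, bone 220) are the package's "moderate noise" condition:
enough degradation that naive thresholding fails, while preserving the
ridge property the pipeline assumes. This is deliberately *not* a wave
simulation: there is no refraction, no depth-dependent attenuation, no
soft-tissue texture, no anatomical variability, and no probe pressure
deformation. Passing tests on these phantoms demonstrates the geometry,
screening, gating, and statistics are correct under the stated noise
model; they say nothing about robustness to clinical image variability,
which requires clinical data.

`renderSequence()` emulates probe drift during continuous scanning: frame
k is the scene rotated by (k−1)·`rotationPerFrame` about the original rim
and translated by (k−1)·`translationPerFrame`, so per-frame ground truth
is exact. Frames listed as off-plane are rendered with ridge contrast
multiplied by 0.3 — a degradation strong enough that quality gating must
reject them, emulating the loss of landmark definition when the probe
leaves the standard plane.

## Quality gates and the dynamic pipeline

"Diagnostic-quality frame" is operationalized as passing all of
(`qualityGates()` defaults):

| gate | default | rationale |
|---|---|---|
| both landmarks detected | — | no geometry without anchors |
| per-landmark confidence | ≥ 0.3 | off-plane contrast ×0.3 falls well below; on-plane moderate noise sits near 0.5–0.6 |
| iliac inclination | ≤ 5° | Graf practice: margin aligned near-vertical |
| iliac-fit RMS residual | ≤ 2 px | clean margin support |
| roof-fit RMS residual | ≤ 3 px | clean roof support; the roof is shorter and noisier |

Gate reasons accumulate rather than short-circuit, so a report lists
everything wrong with a frame. Frames are processed independently — no
temporal smoothing — and sequence aggregates (mean, SD of α) are computed
over diagnostic frames only, with an explicit empty aggregate when none
pass. A frame counts as a *success* when it yields a non-failure α and
passes every gate.

## Statistics

`blandAltmanVsReference()` uses the sample SD (n−1) of the differences and
limits of agreement bias ± 1.96·SD. `iccTwoWay()` implements ICC(2,1) —
two-way random effects, absolute agreement, single measurement — from the
two-way mean squares, with the F-based (Satterthwaite) 95% CI; ICC(2,k)
for rater means is the Spearman–Brown step-up and is labelled as such in
the result. The single-measurement form is the default because
intra-operator tables score individual measurements; reliability reports
that do not name their ICC model are assumed to be of this form. In
degenerate designs (e.g. zero subject variance) the Satterthwaite
approximation can fail; CI bounds then fall back to the admissible range
rather than propagating NaN. One-way ANOVA reports η² = SSB/SST,
Cohen's f = √(η²/(1−η²)), and post-hoc power from the noncentral-F
distribution with noncentrality f²·N at the 0.05 level. Angles are
reported to one decimal and dimensionless effect sizes to two, rounding
half away from zero; stored values always keep full precision, and
rounding happens only at display or report time.

## Degenerate inputs, determinism, problem sizes

Constant frames yield empty maxima sets and empty detections (with a
warning, not an error); all-screened-out peak sets, missing landmarks, and
under-supported roof regions produce reason-coded measurement failures,
never silent numbers. Rendering requires an explicit seed and is
bit-reproducible; the whole pipeline is deterministic given a frame, so
two CLI runs with the same seed and configuration produce bit-identical
JSON.

The test suite and the validation script size their simulations for a
desk-scale run: the headline experiment uses 40 frames at 256×256
(matching a 40-frame validation design), detector properties use 50
seeded frames, line-fit oracles 100 seeded point clouds, and ICC
simulations a 30×4 design with subject/rater/error variances 9/0.5/1.

## Known limitations

* Validation is synthetic-phantom only; clinical variability (anatomy,
  motion, probe pressure, machine settings) is out of scope.
* β-angle measurement and Graf type classification are deliberately not
  implemented.
* The reference detector assumes a single hip in the standard orientation
  (ilium cranial, roof descending medially-leftward); mirrored or
  multi-hip frames need a substituted detector.
* The 5° inclination gate and the residual gates are package definitions
  of "diagnostic quality"; other operationalizations are configurable but
  change what "success rate" means.
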