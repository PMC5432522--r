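---
title: "Models and methods behind cellmon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cellmon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cellmon` turns relief-contrast (oblique epi-illumination) culture images
into quantitative culture-state readouts. This vignette explains the
models the package implements, the defaults it ships with and why, the
synthetic benchmark it is validated against, and the limits of what that
validation shows. Nothing here states an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The imaging model and its simulator

Relief contrast renders an optically thick object as an embossed relief:
a bright leading edge and a dark trailing edge along the illumination
azimuth, on a mid-grey background. The simulator reproduces exactly this
structure. A cell is an ellipse with lognormally distributed projected
area; its axis ratio is solved from a target circularity through the
Ramanujan perimeter approximation, so the analytic truth
(area $\pi ab$, perimeter $P_{\mathrm{Ram}}$, circularity $4\pi A/P^2$)
is known before rasterization. The cell body is an ellipsoidal cap
$h = h_0\sqrt{1-\rho^2}$ whose height scales with the minor axis (capped
at 10 µm). The cap profile is a deliberate choice: a bump whose slope
vanishes at its rim has no optical edge at its geometric boundary, so no
segmenter could recover the analytic truth from such an image; the cap's
steep shoulder puts the visible edge at the true support boundary, which
is also how real cell margins image.

The rendered frame is

$$I = B\,v(x,y) \;+\; g\,\partial_{s} h \;+\; \varepsilon,$$

background level $B$ (default 128), radial vignette $v$, directional
derivative of the height map along the azimuth (default 45°) scaled by
the relief gain $g$ (default 15 luminance units per unit slope), and
Gaussian noise $\varepsilon$ (default SD 3 luminance units), clipped to
`[0, 255]`. The instrument this emulates does not publish its optical
transfer or noise statistics, so these rendering defaults are stated
choices, not measurements.

Ground truth is always computed from the analytic shapes *before*
rasterization; rasterization error is therefore part of what downstream
accuracy tests measure. All generators are bit-reproducible under a seed.

Study conditions baked into the defaults: frames carry 0.463 µm/px
(a 1.2 mm field width on a 2592 px line; the nominal vertical calibration
of the same field differs slightly, so x/y pixel sizes are carried
independently everywhere and areas are computed as
`pixel count × psx × psy`); a 6-well plate has 2 × 3 wells of 9.6 cm²
imaged at 5 regions per well; acquisition runs hourly over the half-open
window [24 h, 72 h), which makes 48 frames per region and 5760 images for
10 regions over 12 passages. The half-open convention is what makes the
arithmetic consistent with that total.

## Segmentation

The pipeline is `flatten_background()` → `texture_energy()` →
`binarize()` → connected components → per-component watershed →
per-cell boundary refinement.

* **Illumination flattening.** The background is a quadratic surface
  fitted to block medians (default block scale 100 µm). Medians ignore
  the zero-mean bipolar relief of the cells, and a quadratic captures
  linear ramps and radial vignettes exactly; the fit degrades gracefully
  to linear or constant when the frame only spans a few blocks. The global
  mean is preserved.
* **Texture energy.** Derivative-of-Gaussian gradient magnitude plus half
  the luminance-amplitude deviation from the median, smoothed at
  `texture_scale_um` (default 1 µm). The two terms are complementary: the
  shading amplitude crosses zero along a band through every cell, where
  the gradient term is large, and vice versa, so their sum is a gap-free
  unipolar cell-presence signal. The map is exactly zero on constant
  input and equivariant under 90° rotation.
* **Thresholding.** Default is a robust noise floor,
  `median + 4·MAD`, rather than Otsu: on sparse fields the energy
  histogram is a narrow noise bulk with a heavy foreground tail, and Otsu
  places its split inside the tail, cutting cells along the
  low-energy band. Otsu remains available and is the right choice for
  frames where foreground dominates (aggregate tracking uses it, guarded
  so it can never fall below the noise floor of a blank frame). Closing,
  hole filling and a `min_cell_area_um2` cutoff (default 30 µm², below
  the smallest cell population the package models) complete the mask.
* **Splitting touching cells.** Distance-transform watershed per
  connected component. The contour is de-wiggled (indicator smoothing)
  before the transform, and the seed-suppression depth is
  `max(h_maxima_depth, 0.25 × max distance)` with `h_maxima_depth = 3` px.
  Both choices respond to a measured failure mode: the medial ridge of a
  large elongated cell wobbles by 2–4 px from boundary rasterization, so
  a fixed 2 px depth systematically oversplits. The cost is sensitivity:
  pairs overlapping by more than a few percent of their area merge into
  one body (their neck is shallower than the wobble floor); touching or
  lightly overlapping pairs split correctly. Watershed flooding and all
  tie-breaks are deterministic.
* **Boundary refinement.** Each detected cell is re-thresholded on a
  fine-scale energy map (`refine_scale_um`, default 0.4 µm) at a half-max
  style fraction (`refine_fraction`, default 0.6) of its own 99th
  percentile energy, and replaced by the convex hull of the result,
  clipped to its own watershed region. The hull restores the interior
  across the zero-shading band and assumes near-convex cell bodies —
  appropriate for rounded-to-spindle culture morphologies, wrong for
  strongly concave ones. Refinement is what brings masks from a
  smoothing-halo-inflated boundary down to the true support; it is
  config-disabled by `refine_fraction = NULL`.

Objects touching the frame border are counted (and included in
confluency) but flagged `border = TRUE`, because their perimeter is
clipped; morphometric summaries exclude them by default. Confluency is
plain foreground fraction.

## Morphometrics

Perimeter uses a four-direction Cauchy–Crofton estimator,
$P = (\pi/8)\sum_\theta n_\theta h_\theta$ over intercept counts at 0°,
45°, 90°, 135°: naive 4-connected boundary counting overestimates
perimeters of smooth shapes enough to bias circularity low by ~20% for a
disc, which would wreck the $4\pi A/P^2$ readout this toolkit is built
around. Diagonal line families use the geometric-mean pixel size, so
strongly anisotropic calibrations are approximate. Circularity is clamped
at 1 with the raw ratio kept in `circularity_raw` (single-pixel objects
exceed 1). Summaries use the sample (n−1) standard deviation.

Profile classification is a quadrant rule on (area, circularity) with
defaults of 150 µm² and 0.5 — boundaries placed between the three
reference regimes the population presets encode (round-small ~80 µm²,
round-large ~330 µm², non-round-small ~60 µm²); ties resolve to the
small/round side. Both thresholds are plain config values.

Operating range: the validated regime is the default population
(200 µm², circularity 0.75, i.e. minor axes of ~10 px at 0.463 µm/px).
Spindle populations at circularity 0.3 have ~3 px minor axes at this
calibration — at the resolution limit, where area and shape recovery
degrade; counting still works.

## Growth

Per-well counts extrapolate the mean of the per-region counts by the
well-to-field area ratio, which assumes uniform density across the well —
the same assumption implicit in averaging a handful of regions. Doubling
time comes either from two endpoints,
$T_d = \Delta t \ln 2 / \ln(N_2/N_1)$ (the convention matching a
two-timepoint protocol), or from a log-linear fit
(`doubling_time_loglinear()`, $T_d = 1/\text{slope}$ of $\log_2 N$ vs
$t$), which is what the noisy-pipeline validation uses. Non-growth
(flat or shrinking counts) is a flagged outcome, not an error. The
manual-vs-automated comparison is a through-origin least-squares fit with
the coefficient of determination computed against the uncentred total sum
of squares; an ordinary-intercept variant sits behind a flag.

The doubling-time benchmark simulates the reference protocol shape —
a 6-well culture monitored from 24 h, Poisson-distributed realized counts,
an expected 30 cells per field at the first frame (seeding density chosen
to reach that per-field count for the 768 × 768 px, 0.463 µm/px frame the
benchmark renders) — sampled every 8 h to 64 h. Six frames over 40 h keep
a 50-replicate run within a few minutes while leaving the median estimate
within a couple of percent of the planted value; counting is empirically
exact frame-by-frame in this density range (≤ ~25% confluency), so the
residual error is Poisson noise, which the median over replicates
suppresses.

## Capillary networks

Skeletonization is distance-ordered homotopic thinning, implemented in
C++ over the exact (anisotropic) squared Euclidean distance transform:
voxels are visited outside-in and deleted when *simple* (removal changes
neither 26-connected object topology nor 6-connected background
topology in the 3×3×3 neighbourhood), with curve endpoints (exactly one
neighbour) preserved. Two implementation details matter and were chosen
after observing concrete failures:

* outside-in ordering keeps medial voxels for last, centring the skeleton
  and preventing thin branches from retracting axially;
* ties in the distance transform are broken by a deterministic hash of
  the voxel index, never raster order — a raster tie-break walks along
  axis-aligned runs and can peel a 2-voxel-wide ribbon from its free end,
  deleting an entire branch while preserving topology at every step.

2-D images run through the same code path as single-slice volumes; the
single-slice simple-point test reduces exactly to 2-D (8, 4) topology.

Graph extraction classifies skeleton voxels by neighbour count, clusters
junction voxels into branch nodes by single linkage within twice the
estimated tube radius (the medial axis of a thick junction fans out over
a ball of about one radius, and the biological quantity is branching
points, not junction voxels), prunes terminal spurs shorter than
1.6 radii (thinning whiskers scale with tube thickness), dissolves
degree-2 nodes (bends are not branches), and bridges each edge across
its junction gap. Edge length is the voxel polyline length after a
light running-mean smoothing of coordinates, which removes the
stair-step overestimate of raw axial+diagonal stepping; tube length
absorbed inside merged junctions is kept in the totals but not as edges.
An optional tip correction extends terminal edges by the residual tip
erosion (axial free distance minus perpendicular radius — zero when the
skeleton reaches the centre of a rounded cap). Isolated components
without edges are reported separately (`n_isolated`), matching the
single-cell-dots readout of failed tube formation.

The benchmark grows random capsule trees (10 segments of 30–80 µm at
radius 5 µm in 2-D; 8 segments of 25–60 µm at radius 4 µm in 3-D,
isotropic 1 µm voxels) with at least 40° between segments sharing a node
and full-segment clearance between unrelated tubes, so the rasterized
topology equals the generating topology. Against that truth the
median absolute total-length error is a few percent and branch counts
are exact; both are asserted in the acceptance suite. Reported
normalization is explicit: totals and per-segment means, labelled as
such.

## Spheroids

Microwell grids are found by matched filtering (disc template at 80% of
the well radius on the median-inverted image) with non-maximum
suppression at 70% of the expected pitch and a nearest-neighbour spacing
check within 10% of the pitch. Aggregate tracking reuses the segmentation
stack per frame with aggregate-scale defaults (Otsu threshold, 4 µm
texture scale, 200 µm² minimum object, no watershed), recording total
projected area, largest-fragment circularity, and fragment count.

Dynamics classification operationalizes three qualitative regimes:
*compacting* (final fragment count 1, final circularity ≥ 0.8, and
non-increasing area trend over the last half of the track, with a 10%
slack on the fitted trend), *dissociating* (fragment count rising to at
least 3× its minimum after an aggregation phase), otherwise *none*. All
three thresholds are config keys; the defaults are this package's
operationalization of behaviours that are described only qualitatively
for the reference cell lines. The simulator builds the matching series —
cells settling into a tight cluster that condenses into a textured dome
of final diameter ~200 µm; a loose aggregate that scatters back into
singles; or static scattered singles — and its truth is measured on its
own noise-free support masks. One rendering choice is worth stating: cell
bodies and compacted spheroids carry interior sub-bumps (nucleus- and
cell-scale texture), because a smooth tall dome is optically flat inside
and would image, unrealistically, as a pure rim.

## Quality-control rules

Per-passage profiles (doubling time, mean area, mean circularity,
final confluency) are evaluated against numeric bands:
`SENESCENCE_SUSPECT` when doubling time and mean area are both at or
above their band highs (growth arrest with cell enlargement), and
`TRANSFORMATION_SUSPECT` when doubling time and area are at or below
their band lows with circularity under the floor (fast, small,
spindle-shaped). Band edges count as out-of-band, so a culture sitting
exactly on a reference boundary is flagged rather than passed. The
defaults bracket a healthy anchor of ~20 h and ~80 µm² with ±30%
(bands 14–26 h and 56–104 µm², circularity floor 0.5); they are
deliberately config-first because no published decision thresholds exist
for this readout. Flagged rows carry an advisory noting that these
patterns have been associated with loss of downstream tube-forming
competence; the package does not claim to predict function — that would
need wet-lab validation.

## What the validation does and does not show

Everything is validated against the package's own simulator: exact
knowledge of every cell, tube and aggregate is what makes counting
exactness, 5%-level morphometry and exact branch counts measurable at
all. The simulator reproduces the geometry and the first-order optics of
relief contrast, but not debris, mitotic rounding, overlapping lamellae,
focus drift, or the real instrument's noise spectrum; passing these
benchmarks demonstrates the correctness and calibration of the
measurement pipeline, not turnkey accuracy on arbitrary real data, whose
segmentation parameters will need adjusting per instrument. Problem
sizes used throughout (512–768 px frames, 50–100 replicates, 6 frames
per growth series) are the package's chosen validation scale; all are
plain arguments.

Known limitations, stated once: heavily overlapping cell pairs segment
as one object; very thin spindle cells are at the resolution limit at
0.463 µm/px; convex-hull refinement assumes near-convex cell bodies;
Crofton diagonals approximate under strong pixel anisotropy; and the QC
bands are operational defaults, not clinically validated thresholds.
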