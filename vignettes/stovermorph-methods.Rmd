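---
title: "Multi-scale morphometrics of pretreated biomass: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale morphometrics of pretreated biomass: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stovermorph)
```

# The measurement problem

Thermochemical pretreatment opens the plant cell wall for enzymatic
digestion, and reactors that add mechanical energy (explosive discharge,
screw shear) disrupt biomass far beyond what identical chemical severity
alone achieves. That disruption is visible at four distinct scales —
particle size reduction in flatbed scans, cell–cell dislocation and wall
swelling in confocal sections, surface roughening in SEM, and intra-wall
delamination/nanofibrillation in TEM — but comparing reactors requires
turning those images into numbers. `stovermorph` implements one estimator
per scale plus the correlation report that ties the structural parameters to
enzymatic glucan release, and pairs each estimator with a synthetic
generator whose ground truth the estimator must recover.

# Estimators

## Particle geometry

Scans are thresholded (Otsu by default; scanned particle fields are strongly
bimodal) and the particle-side pixels labeled with 8-connectivity. With
`split_touching = TRUE`, blobs are first split by a watershed on the
foreground Euclidean distance transform, seeded at its local maxima — the
standard recipe for disconnecting overlapping convex particles. Watershed
seed detection uses a 2 px local-maximum radius and unit tolerance; both are
exposed (`ws_ext`, `ws_tolerance`) because no single setting suits every
particle shape mix. Components under `min_area_px = 4` are discarded as
scanner dust.

Per particle we report area (pixel count × *l*², with *l* the pixel edge
length), perimeter (boundary contour length × *l*), aspect ratio
(major/minor axis of the moment-matched ellipse), and roundness
4·area/(π·major²) — the conventions of the widely used particle-analysis
tools, so values are comparable with the literature. The coordinate
covariance includes the 1/12 px² within-pixel variance term; without it a
single-pixel particle has a degenerate ellipse and roundness diverges, with
it the descriptors of small and square regions match their continuous
counterparts to within rasterization error and roundness stays in (0, 1].

Histogram bins are left-closed (a value on an edge falls to the right), and
out-of-range values are counted separately rather than silently dropped.

## Cell-wall thickness

Two operations in tandem: the boundary-distance map

$$D_B(x,y) = l\,\sqrt{(x-x_B)^2 + (y-y_B)^2}$$

assigns every wall pixel its exact Euclidean distance to the nearest
background pixel, and the medial axis transform (skeletonization) gives the
wall mid-line; sampling $D_B$ at each medial-axis pixel yields one cell-wall
thickness (CWT) value per mid-line pixel, so a single section contributes
hundreds to thousands of measurements. "Nearest boundary" is implemented
with standard distance-transform semantics (nearest *background* pixel); the
alternative reading — nearest background-adjacent foreground pixel — differs
by at most one pixel and is not implemented.

For two cells adjoined across a shared wall, the mid-line value is each
individual cell's wall thickness. For disjoined (dislocated) cells the
mid-line of a single wall sits at half its thickness; the
`"disjoined-doubled"` sampling convention doubles the samples to compensate.
The default is `"raw"`, and reporting both is the caller's choice — on mixed
material neither convention is uniformly right, which is a genuine
limitation of the method, not of this implementation.

The medial axis is computed by Zhang–Suen topology-preserving thinning (no
installed R package provides 2-D skeletonization, and the medial-axis
sampling is the core of this estimator, so it is implemented here and tested
against rectangle/disk geometry and a component-count audit). Skeleton spurs
shorter than 3 px that terminate at a junction are pruned by default:
boundary rasterization otherwise seeds short branches whose distance values
spike the thickness distribution. Pruning never removes open curve ends, so
a simple wall's skeleton is not eaten from its ends; it can be disabled
(`prune_spurs = FALSE`).

Discretization bounds what thickness accuracy is attainable: for a strip of
odd width $w$ the center-row distance to background is $(w+1)/2$, not $w/2$,
so mean raw CWT sits within half a pixel of $w/2$ and tests assert exactly
that band rather than a false exactness.

## SEM surface roughness

Secondary-electron contrast tracks local surface slope, so the dispersion of
gray values over a flat-mounted wall surface is a relative proxy for exposed
surface area (not a height roughness — scanning-probe methods measure that).
The statistic: each square ROI is independently rescaled to the full 0–255
range and the *population* SD of the rescaled pixels is taken; ROI SDs are
then averaged per sample (the reference protocol: six 0.5 µm ROIs × three
micrographs = 18 values, reported as mean ± SD-among-ROIs). Normalization is
per-ROI, taken literally from the protocol; per-micrograph normalization is
the main alternative and would change absolute values but not sample
rankings. Per-ROI rescaling means absolute roughness values depend on each
ROI's realized intensity range — on synthetic Gaussian textures whose range
is itself proportional to sigma the statistic compresses toward
255/(expected range/SD); the ranking-recovery tests therefore anchor each
ROI's range with one 0 and one 255 pixel so the rescale map is the identity
and the statistic reflects the texture SD directly.

Population SD (divide by *n*) rather than sample SD: the difference is
negligible at the ROI sizes used (a 0.5 µm ROI at 0.01 µm/px has 2,500
pixels) and the choice is recorded here and in the function documentation.

## Intra-wall void fraction

In post-stained TEM sections the wall material is dark and voids
(delamination gaps, lumen) are electron-lucent and bright. The threshold is
anchored to a reference ROI known to contain only void space, such as the
cell lumen: $T = \bar{x}_v + k\,\sigma_v$ with $\bar{x}_v, \sigma_v$ the
mean and population SD of the reference region. The multiplier $k$ is
signed and configurable because the rule's literal $+2$ form and the intent
of capturing pixels on the void side of the threshold are mutually
inconsistent for bright voids: with $k=+2$ and bright voids, "above $T$"
excludes ~all of the void population itself. The pipeline default is
$k=-2$ with `polarity = "above"` — the threshold sits two reference-SDs
inside the wall-ward flank of the void distribution, capturing the void
population while a ≥4-combined-SD separation keeps wall pixels below it;
$k=+2$ remains available and [compute_void_threshold()] defaults to the
literal `k = 2` so the formula reads as written. Ties at $T$ are non-void,
consistently with every other threshold in the package. No morphological
cleanup is applied: the classification is pure thresholding, so the
void percentage is exactly a pixel count ratio and monotone in $T$.

Void regions are optionally described with the particle descriptor set;
regions clipped by the ROI border are flagged rather than dropped, since
they contribute to area but their shapes are truncated.

## Correlation report

Each structural/compositional parameter is correlated (Pearson
product-moment, implemented directly and cross-checked against `stats::cor`
in the tests) against glucan release. The default sample set is
`"pretreated-only"`: the untreated control is not a point on the
pretreatment severity–response surface, and parameters such as cell wall
thickness move in opposite directions with and without it (walls swell on
pretreatment but thin with increasing disruption among pretreated samples).
Recomputation from the bundled summary table shows six of the eight
published correlation cells match the three-sample (pretreated-only) choice
at 2 decimals, the particle-size cell is closest to the four-sample choice
(computed −0.96 vs printed −0.97), and the degree-of-polymerization cell
(−0.28) is not reproducible from the printed values under either choice;
both modes are exposed and the mismatching cells are documented rather than
forced. With *n* ≤ 4 samples no p-values are reported — inference at that
size would be decoration. Display rounding is 2 decimals, half away from
zero; unrounded values are always stored.

# Synthetic generators: what they emulate, and what they do not

Every estimator is validated against generators that return machine-readable
ground truth. All are pure functions of their arguments including the seed
(the caller's RNG stream is saved and restored), and all intensities lie in
[0, 255].

* `make_particle_field()` — dark ellipses on a bright background with
  log-normal areas (optionally a two-component mixture emulating the bimodal
  size distribution of unmilled feedstock) and truncated-normal aspect
  ratios; defaults (log-mean 5.5, log-sd 0.6 px²; aspect 1.8 ± 0.4; 2,400 dpi
  calibration, 0.010583 mm/px) give fields resembling milled corn stover
  scans. A `touching_fraction` of particles is placed overlapping a
  neighbour (center distance below the sum of semi-minor axes, so overlap is
  guaranteed); all others are separated by at least 3 px so recovery is
  exact. Not emulated: concave/fibrous particle outlines, illumination
  gradients, scanner noise.
* `make_cell_lattice()` — a rectangular lattice of bright walls of uniform
  thickness on dark lumen; the returned mask *is* the truth. A chosen
  fraction of interior wall segments is split into two parallel sub-walls
  separated by a 1–2 px background gap, emulating middle-lamella
  dislocation. Not emulated: curved walls, wall-thickness variation, cell
  size mixtures, stain intensity gradients — which is why passing the
  half-width recovery test shows correctness of the distance/medial-axis
  machinery, not field accuracy on twisted real anatomy.
* `make_textured_surface()` — i.i.d. normal pixels, clipped to [0, 255];
  clipping biases the realized SD, so truth-recovery uses means ≥ 4σ inside
  the clip boundaries.
* `make_tem_wall()` — elongated void stripes (the intramural banding/
  delamination morphology) occupying an exact pixel-counted share of the
  intra-wall ROI, plus a pure-void reference region. Intensity noise is
  uniform with the requested mean and SD (support mean ± √3·σ). Bounded
  support is deliberate: with Gaussian noise a $k=-2$ reference threshold
  irreducibly misses Φ(−2) ≈ 2.3% of void pixels, biasing recovered
  fractions down by 2.3% of the void fraction (1.7% absolute at 75% voids),
  so recovery error would measure tail mass rather than geometry. With
  bounded laws separated by ≥ 4 combined SDs the threshold classifies every
  pixel correctly and the recovery benchmark isolates the stencil geometry
  — which is the property the estimator is supposed to have. On real TEM
  images, noise tails (and the analyst's choice of $k$) reintroduce a bias
  of this order; users comparing absolute void percentages across studies
  should hold $k$ and polarity fixed.

# Conventions and numerical choices

* ROIs are 1-based with inclusive bounds, matching R matrix indexing
  (`pixels[r1:r2, c1:c2]`).
* Coordinates are row/column (row = image y); multi-channel inputs collapse
  to the equal-weight channel mean; intensities are held as doubles, never
  re-quantized.
* All thresholds are strict with ties classified as background/non-void.
* Constant input to dynamic-range rescaling (and hence to the roughness
  statistic) is an error, not a silent zero: the normalization is undefined
  at zero range.
* Dispersion *among* measurements (SD among ROI SDs, SD of thickness
  samples) uses the sample SD; dispersion *within* a normalization or
  threshold rule (per-ROI roughness, reference-region σ_v) uses the
  population SD.
* Degenerate moment ellipses are floored at 1e-12 before the axis ratio.

# Problem sizes in the test suite

The suite validates on 600×600 px particle fields of 25 particles, 160×160
px 3×3-cell lattices, 200–512 px² textures, 200×200 px TEM images with 36
sub-ROIs per void condition, and 200 random ≤ 32×32 masks for the exact
brute-force distance oracle — sizes chosen so each estimator's error is
dominated by the effect under test (rasterization, sampling noise) rather
than by generation cost, and the whole suite runs in seconds.

# Known limitations

* No 3-D images, no instrument metadata: the pixel length is always
  user-supplied.
* Cell-type selection (e.g. restricting thickness measurements to vascular
  bundle fibers) is manual ROI work upstream, not automated classification.
* The roughness statistic is a relative, normalization-dependent proxy;
  absolute values are not comparable across different ROI sizes or
  normalization choices.
* Published absolute per-sample values (mean thicknesses, roughness values,
  void percentages, particle counts) depend on the original micrographs,
  which are not distributed; the package reproduces the *methods* and the
  correlation table computed from the published per-sample summaries.
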