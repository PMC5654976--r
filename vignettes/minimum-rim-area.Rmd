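---
title: "Minimum rim area of the optic nerve head: sequential and global optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimum rim area of the optic nerve head: sequential and global optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmorim)
```

## The measurement problem

Glaucoma destroys retinal nerve fibres where they leave the eye through the
optic nerve head (ONH). A structural parameter with good diagnostic
properties is the *minimum rim area*: the smallest surface through which
all nerve fibres must pass between the border of the ONH — the Bruch's
membrane opening (BMO) — and the inner retinal surface, the internal
limiting membrane (ILM). Spectral-domain OCT devices acquire radial
"star scans" centred on the BMO (24 radial B-scans at 15°, i.e. 48
half-scan *spokes* at 7.5°), each contributing one BMO point and one
segmented ILM polyline, from which this surface can be reconstructed.

Two optimization strategies exist for the discretized surface, and they do
not give the same number:

* **Sequential (BMO-MRA).** Between every two neighbouring spokes, a
  trapezoid is spanned from the two (fixed) BMO points to one point on
  each ILM polyline, and its area is minimized independently of all other
  sectors. The global and sector values are the sums of the per-trapezoid
  minima. Because neighbouring trapezoids may attach to different ILM
  points on their shared spoke, the resulting surface is generally
  discontinuous.
* **Global (BMO-gMRA).** One BMO-ILM connection point per spoke is
  optimized for all spokes *simultaneously*, under the constraint that the
  two triangles of neighbouring sectors share the connection vertex of
  their common spoke — a continuous triangulated surface. Each inter-spoke
  quad is split into two triangles along a fixed diagonal, and the total
  triangle area is minimized.

Dropping the continuity constraint can only ever shrink the attainable
minimum, so on a matched discretization `MRA <= gMRA` for every scan —
this relaxation bound is a theorem, and the package asserts it on
randomized phantoms rather than merely observing it.

## The optimization machinery

Both strategies search the same space: on spoke $i$, an arclength
parameter $t_i$ along the ILM polyline selects the connection point (the
polyline is parametrized by cumulative arclength, which makes the
parametrization invariant to resampling density). The candidate set is the
polyline vertices densified by a uniform arclength grid (default step
10 µm, `search_options(step = 0.010)`).

For the sequential strategy each quad is minimized jointly over *both* of
its endpoint parameters by exhaustive search over the candidate grid.
The per-quad grid search doubles as a verifiable oracle: the minimum over
an explicit finite set.

For the global strategy the total area decomposes over the cyclic chain of
quads, each coupling only neighbouring spokes, so the exact optimum on the
candidate grid is found by cyclic dynamic programming: condition on the
candidate chosen for spoke 1, solve the remaining open chain by dynamic
programming, close the cycle, and keep the best conditioning. This is
$O(n\,m^2\,m_1)$ for $n$ spokes with $m$ candidates each — exactness over
speed. Ties are broken to the lexicographically smallest candidate-index
vector, which makes results deterministic. The kernel is implemented in
C++ because at $n = 48$, $m \approx 200$ the table sweep is the hot loop.

Both grid optima are then optionally refined in the continuous parameters
by golden-section coordinate descent within one grid step of the current
optimum (cyclic sweeps for the global strategy), accepting only
improvements and stopping when a full sweep gains less than
`refine_tol = 1e-7` mm². Refinement is therefore monotone; the object
records the per-sweep trace (`refine_trace`) and the pre-refinement
`grid_total`, so the monotonicity is testable.

### Chirality

Splitting a warped quad along its two diagonals gives different areas, so
the discretization has a handedness. Following the convention that the
shared-edge orientation reverses between right and left eyes to avoid a
systematic bias, chirality `"A"` (diagonal $bmo_i$–$ilm_{i+1}$) is the
default for OD and `"B"` ($bmo_{i+1}$–$ilm_i$) for OS; both can be forced
explicitly. Mirroring a scan about the vertical en-face axis and flipping
the chirality reproduces the original areas; the package tests this at
$10^{-9}$ mm² on the grid optimum. (After continuous refinement the sweep
order is mirror-reversed, so refined totals agree only to the order of the
refinement tolerance — one reason the refinement tolerance is kept three
orders below the effects of interest.)

### Numerical conventions

* Coordinates are millimetres in a right-handed frame, $z$ axial; OS scans
  are mirrored into the OD orientation on load so one internal convention
  serves everything.
* Degenerate triangles have area 0; no minimum-area solution is ever
  rejected for degeneracy.
* Equal-area grid ties resolve to the smallest arclength parameters
  (sequential) or the lexicographically smallest index vector (global).
* "BMO area" is the area of the BMO point polygon projected onto its
  least-squares plane — the device's internal definition is not public, so
  the package states its own.
* Sector aggregation uses the Garway-Heath layout in the OD frame
  (temporal [315°, 45°), temporal superior [45°, 85°), nasal superior
  [85°, 125°), nasal [125°, 235°), nasal inferior [235°, 275°), temporal
  inferior [275°, 315°)); the exact boundaries used by commercial software
  are not published, so the scheme is configurable. A quad belongs to the
  sector containing the circular midpoint of its two spoke angles, which
  makes the sector sums exactly additive to the global value.

## The synthetic phantom

No public dataset of segmented ONH star scans exists, so the package
generates its own, with known structure:

* an elliptical BMO ring (default semi-axes 0.85 × 0.71 mm, area ≈
  1.9 mm²) sampled at the spoke angles, rigidly tilted by a few degrees;
* per-spoke ILM profiles following a logistic ramp from the cup floor
  ($-$`cup_depth`) to the rim plateau (`rim_height`), centred at the BMO
  crossing radius, with sector-specific multiplicative thinning of the rim
  height and independent Gaussian axial noise (default sd 5 µm, the scale
  of segmentation jitter) on every ILM sample;
* a visual-field mean deviation (MD, dB) generated as a linear function of
  an analytic rim-area proxy (BMO chord lengths × local rim heights) plus
  Gaussian noise.

With the ramp centred at the BMO radius, the ILM passes near the BMO point
itself, and the minimal surface attaches low on the ramp; reaching
clinically realistic global areas (controls ≈ 1.2 mm², glaucoma ≈
0.8 mm²) therefore requires a stylized plateau height of ≈ 0.9 mm for
controls and ≈ 0.72 mm for glaucomatous eyes (with temporal-inferior-
dominated thinning). These defaults were fixed once by running the
pipeline against those area targets; they are conditions of the synthetic
study, not tuning knobs. The phantom reproduces the *pipeline-relevant*
features of real data — scan pattern, realistic BMO area, cup/rim shape
with sectorial loss, segmentation noise, an MD anchored to structure
(Spearman ρ ≈ 0.68 within the glaucoma group) — and none of the image-level
physics (speckle, shadowing, segmentation failure modes, ocular
magnification). Passing tests on phantoms therefore validate the
*optimization and statistics*, not the segmentation of real OCT images.

Cohorts draw per-eye parameters from per-diagnosis distributions under
per-eye RNG substreams derived from a master seed by the eye index, so
cohorts are reproducible and insensitive to generation order; laterality
is drawn 50/50 so the chirality convention is exercised.

## Evaluation statistics

The diagnostic comparison mirrors a paired ROC analysis: Mann-Whitney AUC
(smaller rim area = more diseased, so the default direction is
lower-is-case), the DeLong structural-components test for the paired AUC
difference (identical markers return $z = 0$, $p = 1$ by convention
rather than erroring), partial AUC over specificity 0.9–1.0 reported
*unnormalized* (maximum 0.1, the scale on which such tables print
0.04–0.06), a stratified paired bootstrap for the pAUC difference
(cases and controls resampled separately, pairing preserved; two-sided
normal p on the bootstrap-standardized difference), sensitivity at fixed
specificity using the conservative smallest-threshold-meeting-the-
constraint convention, Spearman correlation with a triple-resampling
bootstrap for comparing two correlations against MD (the comparison method
is the package's choice; no standard exists), and Benjamini-Hochberg
correction with the step-up raw-p threshold.

Resampling is per eye, not per patient; a simulated cohort has no
inter-eye correlation structure, and the clinical analyses this mirrors
did not state a clustering correction either.

Two calibration notes, found while validating the suite at desk scale: the
asymptotic DeLong p agrees with an exact paired swap-permutation oracle to
better than 0.01 at 40 cases + 40 controls (at 20 + 20 the permutation
distribution is too discrete for agreement beyond ≈ 0.03); and the
stratified bootstrap overestimates the spread of the pAUC difference by
≈ 20 % at 30 + 30 — the partial range depends on the top few controls,
an extreme-order-statistic regime where the bootstrap is known to be
conservative — but is calibrated (empirical size ≈ 0.03 at nominal 0.05)
at 60 + 60, the sizes the test suite uses.

## Problem sizes used by the tests

Property tests run on reduced phantoms (10–16 spokes, 20 radial samples,
30–40 µm candidate step) because the properties they assert —
relaxation bound, DP exactness against enumeration, rigid/scaling/mirror
invariances, sector conservation — are size-independent. The closed-form
cylinder, flat and frustum phantoms and the end-to-end study-shaped run
(100 glaucoma + 100 control eyes, 48 spokes, 10 µm step) use full
resolution. The frustum phantom deserves a note: rotational symmetry
collapses its 48 coupled degrees of freedom onto one radius, so a dense
1-D scan provides an independent oracle for the full solver at $10^{-6}$
mm².

## Known limitations

* The continuous refinement is a local coordinate descent; global
  exactness holds on the candidate grid (where it is proven against
  enumeration), and refinement is guaranteed only to never move uphill.
* The phantom's logistic ILM is smooth and unimodal per spoke; real ILM
  segmentations can be multimodal near vessels, which would make the
  per-quad grid oracle even more valuable but is not emulated.
* Per-eye resampling ignores inter-eye correlation (see above).
* The sequential strategy minimizes both trapezoid endpoints jointly;
  whether commercial implementations anchor one endpoint to the
  minimum-rim-width attachment instead is not publicly documented, and the
  two differ in principle.
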