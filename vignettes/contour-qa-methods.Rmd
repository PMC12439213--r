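---
title: "Methods: geometric, dosimetric and timing evaluation of OAR contours"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometric, dosimetric and timing evaluation of OAR contours}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contourqa)
```

## What the package computes

`contourqa` evaluates organ-at-risk (OAR) delineations against a reference
("ground truth", GT) contour set, the standard quality-assurance problem
when AI auto-segmentation is introduced into a radiotherapy workflow. Three
families of measurements are produced:

* **Geometric agreement** between each test contour and the GT, as the five
  metrics conventional in segmentation evaluation: mean surface distance
  (MSD, mm), Dice similarity coefficient (DSC), Hausdorff distance (HD,
  mm), signed volume difference (VD, cc, and relative, %), and
  centre-of-mass difference (CMD, mm).
* **Dosimetric impact**: per-structure DVH summaries (Dmin, Dmax, Dmean,
  Dmedian, Gy) and signed differences between each contour group and the
  GT, judged by the clinical-goal metric of the organ class (maximum dose
  for serial organs and the mandible, mean dose for parallel organs).
* **Workflow statistics**: per-patient contouring minutes summarized as
  medians, percent time saved with and without AI processing overhead, and
  inter-observer variability (pooled SDs per organ, averaged over organs).

All volumetric objects live on an explicit `image_grid`: an array shape, a
positive per-axis voxel spacing in mm, and the mm coordinate of the first
voxel center. Voxel `(i, j, k)` (1-based) has center
`origin + (i-1, j-1, k-1) * spacing`. The z axis increases cranially; this
orientation is load-bearing for the caudal cut-off rule below.

## Geometric metric conventions

Several of these metrics have competing conventions in the literature; the
choices here are fixed and tested:

* **Surfaces.** The surface of a structure is the set of voxels removed by
  a face-connected (6-neighbourhood) binary erosion, with outside-of-array
  treated as background. An isolated voxel is its own surface; a
  1-voxel-thick plate is all surface.
* **Surface distances.** Distances are measured between surface-voxel
  centers via an exact Euclidean distance transform whose per-axis sampling
  equals the voxel spacing (the Felzenszwalb–Huttenlocher separable
  lower-envelope algorithm, implemented in C++). No sub-voxel surface model
  is used. HD is the symmetric maximum of the two directed nearest-surface
  distances. MSD uses the *average-of-directed-means* convention,
  `(mean(Sa→Sb) + mean(Sb→Sa)) / 2`, i.e. the "assd" behaviour, rather
  than pooling both surfaces into one mean. Tests verify both metrics
  against an independent brute-force pairwise oracle to 1e-9 mm on random
  mask pairs.
* **DSC** is plain voxel counting, `2|A∩B| / (|A| + |B|)`; it is an error
  only when both masks are empty (a single empty mask gives 0).
* **VD** is signed, test minus reference, with the *reference* volume as
  the denominator of the relative form.
* **CMD** is the Euclidean distance between occupancy centroids in
  physical coordinates (unweighted voxel mean, scaled by spacing).
* **Caudal cut-off.** Tubular structures whose inferior extent is
  delineation-dependent (the spinal cord analogue here) are truncated, per
  patient, at the most cranial of the caudal ends across the GT *and all*
  contour groups jointly, before any surface metric is computed. Ties make
  the rule a no-op, so no tie-break is needed. The operation is idempotent
  and is applied by the pipeline automatically to organs flagged tubular.
* **Degraded inputs.** Metric functions raise errors on empty masks; the
  pipeline converts these to `NA` records with a machine-readable reason so
  one bad structure cannot abort a cohort run. Aggregations drop `NA`s
  listwise and the dropped counts are logged.

## Dose conventions

Dose and mask must share a grid (a mask grid may be a voxel-aligned window
of the dose grid; no resampling or interpolation is implemented — synthetic
dose is generated directly on the mask grids). Dmax is the absolute
single-voxel maximum within the structure; at the 2.5 mm dose-grid
resolution conventional in treatment planning systems one voxel is
0.0156 cc. Dmedian is the voxel median (mean of the two central values for
even counts), not an interpolated D50% from a cumulative DVH — vendor
conventions differ and the voxel median is the reproducible choice. The
DVH text dialect read by `read_dvh_export()` is a minimal block format
defined by this package as a stand-in for vendor exports, whose layouts are
not standardized.

## Cohort statistics

Group descriptors are the 5-25-50-75-95 percentiles plus mean and sample
SD. Percentiles use linear interpolation between closest order statistics
(R's default type-7 quantile), so the median of an even-sized sample is the
mean of its two central values. SDs use the n−1 denominator everywhere
("observer variability" is the sample SD of a metric pooled over all
patients and observers of a group for one organ); a single observation has
SD 0 in a summary and an undefined (`NA`) variability. Per-organ SDs are
averaged over organs *unweighted* to give the group-level headline.
Percent changes are reported rounded half-away-from-zero to integer
percents (so −43.75% reports as −44%), with the unrounded value retained;
this is the rule consistent with reporting negative reductions. Contouring
times are rounded to the nearest half minute on ingest, ties rounding up.
Cochleas are excluded from geometric aggregation by default (their extreme
relative size discrepancies distort the aggregate scales) but stay in the
dose and time analyses; the exclusion list is configurable.

## The synthetic cohort generator

No clinical data ships with the package; the generator produces a study
with the statistical structure the analysis assumes, so every stage is
testable end to end.

* **Phantom.** Twelve parametric organ analogues of a head-and-neck OAR
  set on a 96×96×64 grid at 2 mm isotropic spacing: ellipsoids (larynx,
  oral cavity, parotids, cochleas, submandibular gland, thyroid), elliptic
  cylinders along z (brainstem, spinal cord, pharyngeal constrictor
  analogue), and a torus arc for the mandible. Organs are rasterized from
  their implicit equations at voxel centers, deterministically. The 2 mm
  default keeps a full cohort run in seconds while leaving ≥ 5 voxels
  across the smallest organs; per-patient anatomical variation is a small
  random translation (SD 2 mm) of organ centers.
* **Observer noise.** An observer contour is the GT re-thresholded after
  shifting its signed distance function by a smooth random field: white
  Gaussian noise smoothed with a ~6 mm Gaussian kernel, rescaled to the
  group's `radial_sd_mm`, plus a constant `systematic_margin_mm`. The
  smoothing length produces spatially correlated boundary errors, which is
  what distinguishes plausible observer variation from voxel shot noise.
  Defaults encode the study conditions the generator emulates: manual
  observers 2.0 mm, adjusted AI contours 0.8 mm (+0.2 mm margin), raw AI
  0.6 mm with a +0.5 mm systematic expansion (AI contours of serial organs
  tend to be slightly generous, and the bias largely survives clinician
  correction). Tubular organs additionally get an integer caudal-extent
  jitter (manual ±2 slices, adjusted ±1, AI 0). The AI group has a single
  output per patient, deterministic given the seed.
* **Signed distance referencing.** The voxel-center signed distance field
  is re-referenced to the estimated continuous boundary by half the mean
  spacing. Without this offset, adjacent voxels sit at |SDF| ≥ one full
  spacing and boundary noise smaller than the voxel size could never flip
  a voxel — sub-voxel noise levels (0.8 mm on a 2 mm grid) would silently
  degenerate to the identity. The offset makes sub-voxel displacement act
  probabilistically on boundary voxels; the cost is a modest discretization
  bias in large margins (a +2 mm margin on a 10 mm sphere reproduces the
  analytic (12/10)³ volume ratio within 10% at 1 mm spacing).
* **Dose.** A deterministic Gaussian falloff field,
  `prescription · exp(−d²/(2·falloff²))`, prescription 68 Gy (2 Gy × 34),
  falloff 25 mm, centered in the pharyngeal region with per-patient jitter.
  This is a stand-in for a planned dose distribution: it has the essential
  property (steep spatial gradient near serial organs) and none of the
  beam physics.
* **Timing.** Per-group log-normal distributions parameterized by median
  and log-dispersion: manual 55 min (sdlog 0.5), adjusted 17 min
  (sdlog 0.4), AI processing + import 10 min (sdlog 0.25). Log-normals are
  used because contouring times are right-skewed; the dispersions were
  chosen once so that a 20-patient draw spans roughly 20–150 min for the
  manual group and 7–40 min for the adjusted group, and are not tuned
  thereafter.
* **Reproducibility.** Every random stream is derived deterministically
  from a master seed and the (group, observer, patient, organ) labels, so
  any single contour can be regenerated in isolation; regenerating a study
  from the same seed is bit-identical, and the generator leaves the
  caller's global RNG state untouched.

What the generator does *not* emulate: CT appearance, anatomical shape
variation beyond rigid translation, guideline-dependent systematic
disagreement between observers (each observer here is exchangeable within
a group), correlation of one observer's errors across organs, and
re-optimized treatment plans. Passing tests on this cohort therefore
demonstrate that the measurement machinery recovers known input parameters
— not that any clinical finding generalizes.

## Performance and problem sizes

The distance transform, erosion, Gaussian smoothing, bounding boxes and
crops are compiled (Rcpp); all pairwise comparisons are evaluated on the
union bounding box plus one voxel, which is exact for every metric used.
Cohort masks are stored on per-organ bounding subgrids (origin-shifted, so
physically identical to full-grid masks) shared by all observers of an
organ; this keeps a default cohort — 10 patients × 12 organs ×
(5 manual + 3 adjusted + 1 AI) observers, 1080 contour pairs — at a few
seconds per full run. The repeated-replicate recovery test in the test
suite runs 100 such cohorts.

## Known limitations

* Surface distances are voxel-center distances; no mesh or sub-voxel
  surface model, and no 95th-percentile HD variant (a candidate
  extension).
* No statistical inference (confidence intervals, mixed-effects modelling
  of the crossed patient × observer design) — the outputs are descriptive
  summaries.
* Mask I/O is NIfTI-1 (via RNifti); DICOM RT-STRUCT is not read. The
  planar-contour JSON dialect and the DVH block dialect are defined by
  this package and documented in `read_contour_json()` and
  `read_dvh_export()`.
* Dose-grid/mask-grid resampling is intentionally absent; inputs must be
  voxel-aligned.
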