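---
title: "Best-match analysis of tibial resections: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Best-match analysis of tibial resections: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resectfit)
```

## The measurement problem

In medial unicompartmental knee arthroplasty (UKA) the tibial component sits
on a planar saw cut. The native medial tibial plateau is typically in about
3 degrees of varus, so a cut made perpendicular to the tibial axis (0
degrees) removes a *wedge-shaped* slab of bone, while a 3-degree varus cut
removes a nearly *rectangular* slab that matches the flat underside of the
component. The removed slab is an exact negative of the cut: CT-scanning it
and rigidly matching its surface against the component's CAD geometry
quantifies how far the cut deviates from the implant — the bone standing
proud of the tray ("elevation", "surplus") is the mismatch that produces
medial overstuffing.

resectfit implements that measurement chain end to end:

1. **Segmentation** (`threshold_mask()`, `otsu_threshold()`, `crop()`,
   `largest_component()`): grey-value thresholding, optional cropping, and
   retention of the single largest connected component (the specimen is
   removed in one piece; anything else is débris or noise).
2. **Surface extraction** (`extract_surface()`): marching tetrahedra on the
   binary mask, yielding a closed, outward-oriented triangle mesh in mm.
3. **Registration** (`initial_align()`, `icp()`): principal-axes
   initialisation refined by trimmed point-to-triangle ICP, bone moving,
   implant fixed.
4. **Distance mapping** (`signed_distance()`, `bin_distances()`,
   `render_views()`): per-vertex signed distance of the bone surface to the
   tray, the eight-band colour code (0–1 voxel light blue, 1–2 dark blue,
   2–3 red, 3–4 green, 4–5 yellow, 5–6 turquoise, 6–7 orange, 7–8 pink),
   and six standardized orthographic overlays.
5. **Compartment analysis** (`partition_compartments()`, `max_elevation()`,
   `totals_and_quotient()`): the matched surface is split into
   anteromedial-medial (AMM), anteromedial-central (AMC),
   posteromedial-medial (PMM) and posteromedial-central (PMC) quadrants;
   per quadrant the maximal elevation is reported, plus totals, total
   mismatch and the central-to-medial surplus quotient.
6. **Sclerosis scoring** (`rotation_correct()`, `most_distal_slice()`,
   `sclerosis_threshold()`, `sclerosis_percent()`): percent sclerotic bone
   in the most distal cut slice using an upper-third grey-value cut-off.
7. **Cohort layer** (`run_specimen()`, `build_cohort_table()`,
   `welch_t()`): per-specimen orchestration and group comparison tables.

All coordinates live in a right-handed mm frame with anatomical axis
labels: +ML towards medial, +AP towards anterior, +PD towards proximal
(slice 1 along PD is the most distal). Compartment laterality is taken from
these labels, never guessed from geometry.

## Surface extraction: variant and accuracy

The extraction is *marching tetrahedra*: each grid cell is split into six
tetrahedra sharing the cell's main diagonal, with a mirror-consistent
decomposition across cell faces. A tetrahedron has no ambiguous sign
configurations, so — unlike classic cube-based tables — the result is
deterministic and watertight by construction; interpolated vertices are
welded by the global edge key so every edge is shared by exactly two
triangles.

Isosurfacing a raw {0,1} field produces staircase facets whose total area
systematically overestimates a smooth body's surface (about +10% for a
digitised sphere, worse for tetrahedral facets). The binary field is
therefore pre-smoothed with a small Gaussian kernel (`sigma = 1` voxel)
before extraction; on a radius-15-voxel digitised sphere this brings both
area and enclosed volume to within 0.4% of the analytic values (the test
suite recomputes this). For masks of only a few voxels the smoothed field
can fall entirely below the iso level; extraction then falls back to the
raw binary field so even a single voxel yields a valid closed mesh.

Two consequences worth keeping in mind:

* Surface positions are quantised: with a binary mask the isosurface sits
  midway between the last inside and first outside voxel, so local heights
  carry a half-voxel uncertainty. Compartment maxima on phantoms are
  accurate to well under one voxel, not to machine precision.
* `smooth_mesh()` (Taubin-style lambda/mu smoothing, volume change < 2% at
  default settings) exists but is **off** by default: the interactive
  surface generators used clinically apply unknown smoothing, so no
  default could claim faithfulness.

## Registration: why trimmed ICP

The bone specimen legitimately overhangs the tray — that overhang *is* the
measurand. An untrimmed least-squares alignment would tilt the bone to bury
the wedge into the component and bias every downstream elevation. `icp()`
therefore discards the worst `icp_trim_fraction` (default 0.1) of
correspondences each iteration, uses point-to-triangle (not
point-to-point) correspondences because bone meshes are much denser than
CAD trays, and evaluates a trimmed RMS that never increases between
accepted iterations (an update that would degrade the fit is rejected and
iteration stops). Correspondences are a deterministic, evenly spaced vertex
subsample (cap 2000), so registration is bit-reproducible without any RNG.

`initial_align()` matches area-weighted surface centroids and principal
covariance axes. Principal axes leave four proper-rotation sign choices;
they are scored by RMS closest-point distance, and near-ties (inevitable
for a symmetric tray, which cannot distinguish a 180-degree flip) are
resolved toward the smallest rotation — both meshes arrive in anatomically
labelled frames, so a large flip is wrong a priori. Even so, a trimmed
alignment of a wedge against a flat tray remains a compromise pose: part of
the wedge is absorbed as a small tilt. The phantom suite quantifies both
regimes: pose recovery on congruent shapes (rotations up to 20 degrees and
translations up to 10 mm recovered to under 0.5 degrees / 0.1 mm) and the
closed-form elevation check, which is run at the generator's ground-truth
pose so that it validates the measurement chain rather than the
registration compromise. The end-to-end cohort analysis runs the full
registered pipeline.

## Compartments and the mismatch summary

The implant footprint's bounding rectangle in the ML–AP plane is split at
configurable fractions (default midpoints) into the four quadrants; a
vertex exactly on a split plane goes to the anterior respectively medial
side, and vertices outside the footprint (dilated by one voxel) are
labelled `outside`. Elevation is the maximum *positive* signed distance per
quadrant — bone below the tray surface is clipped to zero, because only
surplus above the component is measured. Each quadrant lies in one AP half,
so its maximum in the other half is structurally zero and
`total = anterior + posterior` holds exactly.

Two summary definitions were genuinely open and are fixed here as package
conventions:

* **Total mismatch** is the mean of the four compartment totals per
  specimen.
* **The central/medial quotient**
  `(AMC + PMC) / (AMM + PMM)` is computed per specimen and then averaged
  across a cohort (never from averaged totals); a zero denominator flags
  the quotient undefined rather than infinite.

The quotient is scale-invariant, so it isolates the *shape* of the
mismatch: a wedge cut concentrates surplus medially and drives the
quotient below 1.

## Sclerosis scoring

The distal cut face is first rotation-corrected: a least-squares plane is
fitted to the distal surface voxels of the mask (at least 16 required) and
the volume is resampled (trilinear for grey, nearest-neighbour for the
mask) so the plane normal aligns with the PD axis. The analysed slice is
the most distal one holding at least `min_slice_area_fraction` (default
0.5) of the maximal per-slice specimen area — a guard against a ragged,
partially filled last slice.

The cut-off "at the upper third of the grey values" is interpreted as
*range-relative over in-mask pixels of the analysed slice*:
`min + 2/3 (max - min)`, with a quantile-based alternative available
(`sclerosis_rule = "quantile"`). Both the fraction and the rule are
configurable because no standardized cut-off exists for cone-beam CT. The
rule makes the resulting percentage invariant to affine grey rescaling.

A range-relative rule silently presumes a sclerotic class exists. On a
slice with *no* sclerosis the cut-off lands in the upper noise tail of the
single spongious population and reports its tail mass (about 16% at the
phantom noise model) instead of 0. `sclerosis_percent()` therefore applies
a default-on bimodality guard: the in-mask greys are split at their
maximal-between-class-variance point, and sclerotic pixels are only
counted if the two classes separate by at least 4 pooled within-class
standard deviations. A unimodal Gaussian forced into two classes separates
by about 2.7 regardless of sample size, while genuinely bimodal slices at
the phantom grey model separate by about 10, so the margin is wide on both
sides. With the guard, generator fractions between 0 and 0.4 are recovered
with a mean absolute error well under one percentage point.

## The phantom generator

`phantom_spec()` / `make_resection_volume()` build a rounded-rectangular
prism, not an anatomic plateau: every quantity under study (wedge surplus,
quotient, sclerosis fraction, volumes) is geometry-level, and a shape with
closed-form ground truth makes the validation exact where an anatomic shape
would make it unverifiable. Defaults describe a plausible medial tibial
resection: 25 mm (ML) by 40 mm (AP) footprint, 2 mm corner radius, 4 mm
base thickness equal to the tray thickness (so a 0-degree-wedge phantom
matches the tray exactly), 0.5 mm isotropic voxels, grey levels
background 0 / spongious 120 / sclerotic 280 with Gaussian noise of
standard deviation 15, and a sclerotic distal patch fraction of 0.1. The
wedge rises linearly from the central to the medial edge, where its height
is `ml_width * tan(angle)`; voxel centres are offset half a voxel from the
specimen faces so voxelisation is unbiased (the voxel-count volume matches
the analytic prism volume to a fraction of a percent).

Every ground-truth field (voxel count, prism volume, expected
per-compartment maxima, exact sclerotic fraction, tilt transform, distal
slice index) is recomputable in closed form from the phantom spec. All randomness
flows from the spec seed; cohorts derive per-specimen sub-seeds
deterministically from a master seed and jitter dimensions by ±5%.

What the phantoms deliberately do **not** emulate: anatomic plateau shape,
cortical shells, CBCT physics (beam hardening, scatter, partial-volume
grey ramps), metal artefacts, or formalin-related changes. Passing the
phantom suite therefore demonstrates that the measurement chain is
correct and unbiased on known geometry — not that segmentation thresholds
or registration will be trouble-free on clinical scans.

Following the clinical convention, the cohort generator's "0-degree" group
carries the *wedge-shaped* phantoms (a perpendicular cut on a varus joint
line) and the "3-degree" group the rectangular ones.

## Numerical choices and degenerate inputs

* Threshold bands are half-open `[low, high)`, so stacked bands never
  double-count.
* `otsu_threshold()` maximises between-class variance on a 256-bin
  histogram; an empty valley between classes produces exactly tied
  criteria, and tied bins are averaged so the threshold sits mid-valley.
* Connected components default to 26-connectivity (most permissive, right
  for one-piece specimens); size ties break toward the lexicographically
  smallest minimal voxel index.
* Distances: closest points on triangles by Voronoi-region case analysis;
  sign from angle-weighted pseudonormals, which classify inside/outside
  correctly even when the closest point lies on an edge or vertex of the
  tray mesh.
* Distance units default to voxels (the conventional reporting unit for
  this analysis); mm values are always stored alongside.
* Degenerate inputs error early and explicitly: empty masks, constant
  volumes (Otsu undefined), coplanar meshes (principal axes undefined),
  open meshes for volume computation (volume reported `NA` with a
  warning), fewer than 16 distal surface voxels for the plane fit.
* Renders use a deterministic software z-buffer (no graphics stack), so
  identical inputs give byte-identical PNGs; oblique views are fixed at
  ±45 degrees azimuth from anterior at 30 degrees elevation.

## Problem sizes

The shipped validation uses digitised spheres of radius 15 voxels, 50
random mesh pairs against an exhaustive brute-force distance oracle, 20
seeded registration perturbations, wedge phantoms at 0.5 mm voxels (about
10^5 voxels, ~4 x 10^4 surface vertices), nine sclerosis fractions at
10^4-pixel slices, and an end-to-end cohort of 10 + 10 phantoms. These
sizes keep the full suite and the acceptance script in the range of a
minute or two on one CPU while leaving every tolerance comfortably
non-marginal.

## Known limitations

* The mask-based surface carries half-voxel height quantisation; sub-voxel
  elevation accuracy would require grey-level (partial-volume) isosurfaces.
* Trimmed ICP reduces but does not eliminate pose absorption of the wedge;
  reported compartment maxima after full registration are mildly
  conservative for strongly wedged specimens.
* The DICOM reader supports explicit-VR little-endian single-frame series
  only — enough for generic exports; DICOM writing is out of scope.
* Group comparisons are per-row Welch t-tests at 0.05 without multiplicity
  correction (a correction flag exists but defaults off, matching the
  analysis convention this package mirrors).

## A minimal worked run

```{r example, eval = FALSE}
spec <- phantom_spec(wedge_angle_deg = 3, seed = 5)
ph <- make_resection_volume(spec)
tray <- make_implant_mesh(spec)
res <- run_specimen(ph$volume, tray, out_dir = "demo_out", id = "demo")
print(res)
res$compartments$totals
```
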