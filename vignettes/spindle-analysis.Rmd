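---
title: "Quantifying spindle microtubule organization from spatial graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spindle microtubule organization from spatial graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Electron tomography of mitotic cells produces complete filament models of
the spindle: every microtubule as an ordered 3D polyline, annotated with a
label marking the kinetochore microtubules (KMTs) and, optionally, with the
k-fiber each KMT belongs to.  These models arrive as AmiraMesh ASCII
`HxSpatialGraph` files.  The biology lives in their geometry: how long are
KMTs, how straight, do k-fibers twist around the pole-to-pole axis, how
tightly are KMTs packed, where do minus-ends nucleate from neighboring
microtubules, and which microtubules run close enough to interact through
crosslinkers.  `spindlegraph` computes these quantities reproducibly from
the raw file.

## Input standardization

Raw segmentations are heterogeneous: arbitrary point spacing along tracks,
an arbitrary global orientation, no explicit polarity.  Three preprocessing
steps standardize them.

**Resampling** (`resample_uniform()`, default 20 nm).  Every analysis that
walks the lattice in arc-length steps or reasons about contact runs assumes
roughly uniform point spacing.  The resampled track lies exactly on the
original polyline (no smoothing), endpoints are preserved, interior points
sit exactly 20 nm apart with one shorter final interval.  A track shorter
than one spacing collapses to its endpoints and is flagged degenerate
rather than dropped.

**Reorientation** (`reorient_to_axis()`).  One proper rigid transform maps
pole 1 to the origin and the pole-to-pole line onto the +z axis (the axis
is configurable).  The stated requirement is only that both poles agree in
the off-axis coordinates; fixing the frame completely (pole 1 at the
origin) makes outputs comparable across spindles.  Reflections are never
used — they would flip the sign of twist and helicity, which are chiral
quantities.  When pole positions are not supplied they are estimated from
the KMT geometry: the outer (poleward) KMT endpoints are clustered by
hemisphere along the first principal axis of the model and averaged.  This
is accurate enough to orient the spindle, but note that KMT minus-ends stop
short of the centriole pair, so estimated poles sit slightly inside the
true poles; supply measured pole coordinates when they are available.

**Polarity and classes** (`infer_plus_minus_ends()`, `build_kfibers()`,
`pair_sister_kfibers()`).  KMT plus-ends terminate at kinetochores near the
spindle equator and minus-ends point poleward, so for each KMT the end
axially farther from its pole is the plus end; exact ties are broken toward
the stored first point and flagged.  Fibers are built from the per-edge
membership label.  Sister fibers are paired by mutual nearest plus-end
centroids on opposite poles, accepted only when the two pole-to-centroid
directions are antiparallel within a 60° cone ("facing each other"); the
cone and the mutual-nearest rule are this package's operationalization of
sister detection, and ambiguous fibers are left unpaired with a warning
rather than force-paired.

## The metrics

**Length** is the sum of consecutive point distances.  **Tortuosity** is
arc length over endpoint chord: exactly 1 for a straight track, π/2 for a
half-circle; the local variant slides a 500 nm arc window along the track
(the same step the twist analysis uses, so profiles align).  A closed track
(coincident endpoints) reports `Inf` and is excluded from summaries.

**Twist** is measured in 500 nm arc-length steps from the plus end.  At
each step every member KMT has a radial vector from the fiber center;
projecting consecutive radial vectors into the plane normal to the local
center-curve tangent and taking the signed angle between them gives that
KMT's local twist, and the fiber's local twist is the mean over members.
The printed source formula is a scalar arctangent of two vector symbols;
the signed planar angle via the two-argument arctangent of (cross, dot) is
the numerically stable reading and keeps the sign.  Two details matter:

- The center used for a step pair is the mean over the KMTs present at
  *both* steps.  Members end at different arc positions; if a member
  drops out between steps and the center were taken over all present
  members, the center would jump and manufacture spurious rotation.
- The sign reference is the local tangent oriented along the pole-to-pole
  axis direction, so handedness does not depend on which pole the fiber
  points to.  Positive twist is a right-handed rotation about the
  pole-1→pole-2 direction; mirror reflection flips every sign.

**Helicity** treats the fiber center curve as a single path and measures
its rotation about the pole-to-pole axis, divided by the center-curve
length, in °/µm.  Twist and helicity deliberately use different reference
frames (fiber frame vs. pole axis frame) — both are reported, and users
should not expect them to agree: a fiber can twist internally without
winding around the spindle axis and vice versa.  For an ideal helix of
pitch p about the axis, helicity approaches 360/p °/µm as the radius/pitch
ratio shrinks; at radius/pitch = 0.02 the arc-versus-axial correction is
below 1%.

**Cross-section area and density.**  At each center-curve step the member
KMTs are intersected with the plane normal to the local tangent (linear
interpolation on the crossing segment; a KMT tangent to the plane
contributes its nearest point if within half the resample spacing),
projected to 2D, and the alpha-shape area is computed.  The alpha complex
is built on a Delaunay triangulation written for this package
(Bowyer–Watson with the flood-fill cavity variant; no 2D Delaunay
implementation was available among the package's dependencies): the area is
the summed area of triangles with circumradius at most the alpha radius,
and `alpha = Inf` reproduces the convex hull exactly.  Fewer than three
crossing KMTs, or collinear crossings, give `NA` — not 0, which would make
densities dishonest.  Density is the crossing count divided by that area,
per µm².  The default alpha is `Inf` (convex hull); a finite alpha around
1–2 KMT spacings tightens the outline of concave bundles.

**Branching and interactions.**  Distances are segment-exact (point to
segment, not point to sampled vertex): at a 25 nm branching threshold, a
20 nm sampling alone could inject up to 10 nm of error, so vertex-sampled
distances would make detection depend on the resampling density.  Each KMT
minus-end reports at most its single closest other microtubule, with ties
broken toward the lower id for deterministic output.  Interaction mapping
reports one record per maximal contiguous run of source sample points
within the threshold of the target, with the run's start position and
arc-length extent measured on the source side (the source/target choice is
not specified by the underlying method description; source-side is used and
documented here).  Candidate pairs are pruned with axis-aligned bounding
boxes expanded by the threshold; the pruning is exact, and the unpruned
all-pairs path is retained (`brute_force = TRUE`) and tested to produce
identical records.

## The synthetic generator

`generate_spindle()` emulates the input the metrics assume: two poles on
the axis, kinetochore pairs on a metaphase plate disc (golden-angle
layout), one k-fiber per kinetochore whose KMTs are helices (or straight
lines) about the fiber axis, background non-KMTs, and optionally planted
branch events constructed by placing a non-KMT at an exactly known
perpendicular distance from a chosen minus-end.  Defaults are a small
HeLa-like metaphase spindle: 10 µm pole-to-pole, 10 fiber pairs on a
2.5 µm plate, 9 KMTs per fiber on a 60 nm ring, KMT lengths 4 ± 1 µm
(truncated to the kinetochore-to-pole distance), 1 µm inter-kinetochore
distance, 40 non-KMTs of 2 ± 0.8 µm.

Noise is isotropic Gaussian per trace node (default σ = 5 nm), applied to
raw nodes spaced 250 nm apart — the scale of real trace control points —
*before* the analysis-side 20 nm resampling.  This matters: i.i.d. jitter
applied at 20 nm spacing would be high-frequency roughness no real tracing
produces, and it would bias arc lengths upward by roughly
√(1 + 2σ²·3/d²) − 1 ≈ 17%; at 250 nm node spacing the same jitter biases
lengths by under 0.1%.  A separate `kin_jitter_nm` perturbs each
kinetochore position independently, which is the natural way to model
centroid-level uncertainty in sister pairing.

What the generator does *not* emulate: curved non-KMT trajectories,
serial-section stitching artifacts, missing or broken tracks,
length-dependent tracing error, and realistic minus-end clustering at the
pole.  Passing the recovery suites therefore demonstrates that the
estimators are unbiased on clean geometry of known truth, not that they are
robust to every segmentation pathology.

## Numerical choices and degenerate inputs

- File round trips are exact: coordinates are written with full double
  precision (`%.17g`), so read(write(g)) echoes every value bit for bit.
- Indices are 0-based on disk (the file format's own convention) and
  1-based inside R.
- The Delaunay super-triangle is placed 10³ box-lengths out: far enough
  that boundary sliver triangles with large circumcircles are not clipped,
  near enough that the incircle predicate keeps full precision.  Ties
  (cocircular points, e.g. four KMTs on a square) are resolved by the
  flood-fill cavity, which keeps the triangulation consistent.
- Duplicate consecutive points are removed on construction; microtubules
  with fewer than two distinct points are rejected.
- Fibers whose center curve spans fewer than two 500 nm steps report `NA`
  helicity with a warning; single-KMT fibers use their own track as the
  center curve, and multi-KMT center curves are truncated where fewer than
  two members remain.
- Correlations in the KMT-number table are descriptive (both Pearson and
  Spearman, no multiplicity correction); fewer than three fibers, or a
  zero-variance covariate, give `NA` with a flag.

## Problem sizes used by the test suites

The validation suites run on simulated spindles of 2–12 fibers with 2–9
KMTs each plus tens of background microtubules, and on 50 randomized
instances of 8–14 microtubules for the brute-force equivalence checks —
sizes where the independent oracles (dense 0.1 nm sampling, scalar
all-pairs distance loops, `grDevices::chull`) are themselves fast and
trustworthy.  All kernels are vectorized over segments, and full-size
spindles (thousands of microtubules) are handled by the same code paths;
the bounding-box pruning keeps the interaction search near-linear in the
number of genuinely close pairs.

## Known limitations

- XLSX table output is part of the historical viewer contract but is not
  produced by this package; CSV (plus a JSON manifest) is the canonical
  output, and the viewer accepts CSV.
- Binary AmiraMesh files are rejected; only the ASCII dialect is parsed.
- Pole positions are best supplied explicitly; the built-in estimator
  recovers the axis direction well but places poles at the KMT minus-end
  centroids, slightly inside the true poles.
- Tortuosity is the only curvature measure (no Frenet curvature
  profiles), and interaction records do not model microtubule radius or
  infer crosslinkers.
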