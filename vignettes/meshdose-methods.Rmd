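---
title: "Methods: mesh-based dose estimation in meshdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mesh-based dose estimation in meshdose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meshdose)
```

`meshdose` implements a correction-based dose chain on triangular organ
meshes. This vignette documents the models, the parameters that matter,
the numerical choices, and what the synthetic phantoms do and do not
demonstrate.

## From labeled points to organ models

The refinement chain assumes the input is a *volumetric* labeled point
cloud in physical millimetres — one point per retained CT voxel, as
produced by `volume_to_cloud()` — together with a sparser labeled
prediction of the same anatomy. The stages are:

1. **Label propagation.** Each dense point takes the modal label among
   its `knn_label = 10` nearest sparse points (Euclidean metric in mm —
   anisotropic slice spacing is already baked into the coordinates).
   Ties are broken by the single nearest neighbour's label: local,
   deterministic, and exact when the vote is unanimous.
2. **Statistical outlier removal.** The per-point statistic is the
   *mean* distance to the `knn_outlier = 30` nearest neighbours;
   points above the global mean plus `sd_factor = 2` standard
   deviations are dropped. The mean (rather than the max or the full
   distance set) makes the statistic smooth in the point position and
   order-free; the global threshold is computed once, with no
   iteration. On a perfectly clean, regularly gridded cloud this rule
   trims a thin boundary shell (boundary points have one-sided
   neighbourhoods); this is inherent to the rule, costs a few percent
   of volume at CT resolution, and is the main reason the pipeline's
   volume accuracy is quoted at CT spacing rather than on coarse grids.
3. **Voxelisation.** Binary occupancy under the voxel-centre
   convention: the physical coordinate of voxel (i, j, k) is
   `origin + (i,j,k) * spacing`, and a voxel is occupied iff at least
   one point of the organ maps into it. The default spacing
   (0.97656, 0.97656, 2.99) mm matches the in-plane resolution and
   slice spacing of the source imaging protocol. Two padding voxels
   guarantee the above-iso region never touches the grid boundary, so
   the extracted surface is closed.
4. **Isosurface extraction.** The surface at `iso_level = 0.5` is
   extracted by tetrahedral decomposition: each grid cell is split into
   six tetrahedra sharing the main diagonal, chosen so the split is
   mirror-consistent across shared cell faces, and each tetrahedron
   contributes 0–2 triangles with vertices linearly interpolated along
   cell edges. Vertices are deduplicated exactly by the grid edge they
   lie on, so the mesh is watertight by construction and triangle
   orientation is fixed per-triangle to point away from the occupied
   side. On binary occupancy the surface passes through edge midpoints:
   a single occupied voxel yields its dual polyhedron (volume half the
   voxel), and enclosed volumes converge to truth as spacing shrinks
   (a 20 mm sphere at 1 mm spacing is recovered within 0.5 %).
5. **Laplacian smoothing.** `smooth_iterations = 80` passes of
   v ← v + `relaxation`·(mean of 1-ring neighbours − v) with
   relaxation 0.1 and uniform (umbrella) weights, since only "average
   of neighbouring vertices" semantics are assumed. Umbrella smoothing
   contracts the surface slightly (curvature-proportional); at CT
   resolution the contraction is a fraction of a millimetre, well below
   the noise it removes, but on very coarse meshes shrinkage can
   dominate — a property users should keep in mind when smoothing
   low-resolution models.
6. **Largest component.** Vertex-connected components are found by
   union-find; the component with the most faces survives, ties broken
   by total area. This removes both detached fragments and interior
   cavity shells left by sampling holes.

Accuracy is scored by `dice()`, with an explicit error when the organ
is absent from both labelings (0/0 is undefined, not zero).

## Beam geometry and ray casting

A beam axis is a single ray — the divergent field is not modelled,
matching the depth-and-dose-at-a-point scope of the chain. The gantry
convention is declared rather than assumed: rotation in the axial x–y
plane about the patient's longitudinal z axis, gantry 0° entering
anteriorly with the source at `isocenter + (0, −SAD, 0)`, angles
increasing toward the patient's left. All geometry is in mm; dosimetry
depths are in cm, converted at exactly one point
(`effective_depth()`), which keeps unit errors testable.

Ray–mesh intersection solves the plane equation per face and applies
the cyclic same-side point-in-triangle condition, with edge and vertex
contact counting as inside. Numerical policy:

* ε = 1e−9 mm rejects parallel planes and hits at the origin
  (double-precision geometry at mm scale);
* ε_merge = 1e−6 mm merges duplicate hits from shared-edge crossings,
  so a ray through an edge counts once;
* crossing parity is the source of truth when pairing entry/exit
  points: entering/exiting flags follow the sign of r̂d·n̂, but
  isosurfaced meshes can carry local winding flips, so mismatched
  alternation is repaired by position parity instead of failing. An
  odd crossing count is a hard error naming the offending organ — it
  means the mesh is open.

Where organ meshes are spatially nested (a tumour inside a lung), path
segments are resolved by priority: the traversal is cut at every
boundary and each elementary interval is assigned the highest-priority
covering organ. The default priority is increasing mesh volume, so
nested structures carve their hosts — the natural reading when a
smaller organ is physically embedded in a larger one.

## Depth dose, SSD corrections, heterogeneity

The buildup-tail shape d/(d² + n)·e^(−μd) multiplies a quadratic
buildup by an exponential attenuation tail. It is treated strictly as a
*shape*: `pdd()` normalises it to 100 % at its own peak, which is
located by golden-section search on (0, 50] cm to 1e−6 cm (the
closed-form stationarity condition is a cubic; the bracketed search is
simpler and robust across the whole (n, μ) range, and the tests verify
the optimum against dense grid scans; in the μ → 0 limit the peak is
at √n). The demonstration parameters n = 2.25 cm², μ = 0.0465 cm⁻¹
give d_max ≈ 1.4 cm, a 6 MV-like curve; they are illustrative defaults,
not measured beam data, and `fit_pdd()` exists precisely so users can
calibrate (n, μ) per energy and field size from measured curves
(Levenberg–Marquardt on the normalised shape; depths must span both
sides of the peak or the fit aborts as unidentifiable).

SSD dependence uses the explicit inverse-square form with the scatter
factor K_s as a calibration input defaulting to 1 (it is named in the
formalism but has no universal value). The Mayneord factor is, by
construction, the ratio of the two SSD-explicit curves — the test suite
asserts this to 1e−12 over random inputs rather than trusting the
algebra.

One formulary discrepancy is surfaced rather than silently resolved:
the SSD output factor is implemented as
((SSD0 + dref)/(SSD + dref))^exponent with `exponent = 2` (standard
inverse-square practice, consistent with the squared terms used
everywhere else in the chain), while some printed formularies carry the
first power. The exponent is an explicit argument, so either reading is
available.

Heterogeneity uses the effective-depth rescaling d_eff = Σ zᵢ·ηᵢ with η
the water-equivalence coefficient per organ (soft tissue and bone
lumped at η = 1, lung 0.275, heart ≈ 1 — mass-density proxies). Gaps
between traced segments inside the body count at η = 1. This is a
first-order path-length correction: it captures transmission through
low-density lung but no scatter rebuild-up, lateral disequilibrium, or
interface effects — which is exactly why the lung case disagrees with a
full TPS by double digits while homogeneous sites agree to a few
percent.

## LKB scoring and beam selection

The DVH reduction, the t statistic and NTCP = Φ(t) follow the standard
LKB chain. The volume dependence of the tolerance dose is written
TD50(v) = TD50·v^(−n) — the conventional power law, adopted as the
interpretation of the bare "TD50(Vol_eff)" notation. Φ is evaluated by
`stats::pnorm`, cross-checked in the tests against a Maclaurin-series
erf to 1e−12. DVHs are an *input* type (equal-volume point samples or
explicit bins): the package computes point doses along beam axes, not
3-D dose grids, so it cannot build whole-organ DVHs from imaging.

For serial organs the relevant summary is the maximum-dose point along
the traversed interval, which for a monotone-past-peak curve is the
effective depth clamped to d_max. For parallel organs the
depth-versus-gantry-angle area under the curve (trapezoidal) ranks
beam arrangements: lower total depth ≈ less irradiated volume.

## Collision detection

Every machine part and the patient carry world-frame axis-aligned
bounding boxes recomputed per pose and inflated by a 50 mm safety
margin on all sides. Recomputing AABBs after rotation deliberately
enlarges boxes of rotated parts — the scheme is conservative by design
and will flag tight-but-safe configurations. Overlap is the
separating-axis test specialised to AABBs (the three coordinate axes
are the only candidates), with touching faces counting as collision
(the safe tie-break). The BVH (median split on the longest centroid
axis) is a pure accelerator: its pair list is asserted identical to
brute-force all-pairs on every random scene in the suite. The
kinematic model is minimal — gantry rotation about the isocenter axis,
couch translation plus yaw — and pairs adjacent in the kinematic chain
are exempt from testing.

## What the synthetic phantoms show — and what they don't

All fixtures are generated in code. The thorax phantom is a set of
nested quadrics (body 35 × 20 × 40 cm, lungs 9 × 7 × 19 cm at η = 0.275,
heart, 1.5 cm tumour in the left lung) sized to clinical plausibility;
every beam entry/exit point has a closed form, which is what makes the
ray-casting and effective-depth tests *oracles* rather than regression
snapshots. Point clouds are uniform samples (or CT-like grid points)
with isotropic Gaussian noise and planted outliers pushed 5–10 noise
standard deviations outside the surface (with a 2 mm floor so the
noiseless case still has genuine outliers).

Passing these tests demonstrates geometric and algebraic correctness of
the chain. It does **not** demonstrate anatomical realism (no organ has
quadric shape), CT intensity realism (HU is constant per organ),
segmentation quality (the network stage is out of scope — the pipeline
consumes any sparse prediction), or dosimetric accuracy beyond the
correction-based model class (no Monte Carlo or
convolution–superposition reference is computed).

## Problem sizes and runtime

The suite and the acceptance script are sized for a single CPU: the
pipeline check uses an 80 × 60 × 50 mm organ at CT spacing (~44 000
points, ~12 s end to end); chord and triangle agreement use 25 rays and
10 000 random triangles; BVH-vs-brute-force equivalence uses 100-box
scenes over 100 seeds. The full test suite runs in about half a
minute.

## Known limitations

* Single-ray beams: no field-size, penumbra or MLC modelling; the
  field size on `pdd_model()` is bookkeeping for per-(energy, field)
  calibration, not an analytic dependence.
* Effective depth is a first-order heterogeneity correction; expect
  double-digit percent deviations from a full TPS inside and beyond
  low-density lung.
* Statistical outlier removal trims thin boundary shells of perfectly
  clean clouds; at coarse voxel spacing this bias is visible in
  reconstructed volumes.
* AABB collision boxes over-approximate rotated parts; flags are
  conservative, never permissive.
* NIfTI ingestion requires axis-aligned direction cosines; oblique
  volumes must be reoriented upstream.
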