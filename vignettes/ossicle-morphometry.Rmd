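---
title: "Automated 3D morphometry of the ossicular chain: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated 3D morphometry of the ossicular chain: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ossimetry)
```

## The measurement problem

The three middle-ear ossicles — malleus, incus and stapes — form the chain
that conducts sound from the eardrum to the oval window. Reconstruction
surgery and prosthesis sizing need accurate preoperative measurements of
this chain, classically taken by hand on multiplanar CT views: slow,
operator-dependent, and impractical at scale. Given a labeled
ultra-high-resolution CT volume (isotropic grids around 0.1 mm, one integer
label per ossicle), `ossimetry` computes the twelve standard parameters
automatically:

| parameter | letters | meaning | units |
|---|---|---|---|
| malleus total height | AC | head apex to manubrium tip | mm |
| manubrium length | BC | lateral process to manubrium tip | mm |
| head and neck length | AB | head apex to lateral process | mm |
| incus total height | DG | body top to long-process tip | mm |
| incus total width | EF | body to short-process tip | mm |
| process distance | FG | long- to short-process tip | mm |
| stapes total height | GI | head to footplate bottom | mm |
| footplate length | HJ | footplate major axis | mm |
| incudostapedial joint angle | ∠DGI | at the incus long-process tip | degrees |
| ossicle volumes (3) | — | per reconstructed mesh | mm³ |

All geometry is computed in physical millimetre coordinates
(voxel-centre convention, `origin + index * spacing`), so anisotropic
inputs cannot silently distort distances; they are accepted with a warning
because the intended inputs are isotropic.

## Pipeline

Each ossicle label runs through three stages.

**Surface reconstruction.** The binary mask (largest 26-connected
component; smaller islands are logged) becomes an exact signed Euclidean
distance field with a half-voxel boundary offset, is refined, and is
triangulated at the zero level by a marching-cubes-family extractor on a
six-tetrahedra (Kuhn) decomposition of each cell. The tetrahedral
decomposition is conforming across cells, so the mesh is watertight by
construction with no ambiguous cases, which the landmark stage relies on.
The mesh is then low-pass filtered with a Hamming-windowed sinc
approximation of the ideal low-pass in the umbrella graph Laplacian
(Chebyshev recurrence, degree = `smooth$iterations`); unlike plain
Laplacian averaging this filter has near-unit gain below the pass band, so
staircase noise is removed with volume drift well under 1% on reference
spheres.

The subvoxel refinement step deserves a note. Plain mean-curvature motion
is a shrink flow: at 0.1 mm resolution it visibly erodes crura (radius
about 0.2 mm) and footplate rims, biasing stapes volume by several percent.
We therefore evolve the field by the *deviation* of curvature from its
local 3-voxel box average, `phi <- phi + dt * w * (kappa - kappa_bar) *
|grad phi|`. Staircase artefacts oscillate around the local mean and are
flattened; constant-curvature anatomy (tubes, caps, plates) generates no
net motion. Two safety rails bound the step: curvature is clamped to twice
the grid Nyquist value `1/h`, and after every iteration the field is
clamped into a hard fidelity band (default half a voxel) around the input,
so the refined surface can never drift farther than the band from the
original mask boundary regardless of iteration count. Defaults
(`iterations = 2`, `smooth_weight = 0.5`) keep the explicit step stable;
the deviation flow behaves like a higher-order diffusion and oscillates if
stepped too aggressively.

**Feature point identification.** Per-vertex discrete curvature uses the
angle-deficit formula for Gaussian curvature with mixed Voronoi vertex
areas (the Meyer et al. obtuse-triangle safeguard; barycentric areas
misjudge the support of vertices ringed by the skinny triangles that
tetrahedral extraction produces, and inflate curvature) and the
cotangent-Laplacian magnitude with outward-normal sign for mean curvature.
On closed genus-0 meshes the raw angle deficits sum to 4π, which the tests
assert to 1e-6. Because pointwise discrete curvature on irregular
extraction meshes carries mesh-scale noise, both maps are smoothed by two
rounds of graph-neighbourhood averaging before any thresholding; uniform
fields are untouched, single-vertex spikes flatten. Convex protrusion tips
are strict local maxima of (smoothed) Gaussian curvature above `min_gauss`
with positive mean curvature, non-maximum suppressed within `nms_radius`,
and gated on support-area reliability (vertices whose mixed area falls
below a tenth of the median are micro-triangle clusters, not geometry). The oriented bounding box is
PCA-initialized and refined by deterministic coordinate-descent rotation
search over support points (extremes in a fixed spherical Fibonacci
direction set); it is near-minimal — never worse than the PCA box, and
within 1% of a dense rotation-grid search on box fixtures — and fully
deterministic, which matters for reproducibility. Exact farthest vertex
pairs are found with bounding-box pruning in a PCA-aligned frame and are
verified against an O(n²) oracle in the tests.

Landmark rules, per ossicle:

* **Malleus**: (A, C) is the global farthest pair; A is the end with the
  larger local cross-section (90th-percentile radial distance in a 0.75 mm
  end slab — the head is thicker than the manubrium tip). B is a protrusion
  tip in the central half of the principal-axis extent; among candidate
  tips we take the one *farthest from the AC chord* rather than the
  highest-curvature one, because voxel-scale curvature spikes can rival a
  real process in curvature but always hug the axis, while the lateral
  process protrudes by millimetres. A minimum protrusion of 1.2 mm is
  required (above the head-radius noise ceiling); below it the case is
  rejected as landmark-B-not-found,
  mirroring the clinical exclusion of incomplete segmentations. The
  selected tip is then refined locally to the apex (maximizer of
  chord distance within 0.6 mm).
* **Incus**: (D, G) is the farthest pair, with G the end nearer the stapes
  head when one is available (or the thinner end otherwise; ambiguity is
  flagged). F is the tip farthest from the line DG, refined to the apex as
  the local maximizer of distance from the body centroid. E maximizes
  distance to F over the body region (projections along the DG chord
  nearer D than the DG midpoint).
* **Stapes**: the footplate seed is the largest connected near-planar
  vertex cluster (|H| < `planar_h`, plane-fit RMS < `planar_rms`); a
  perforation may legitimately fragment the flat face into arcs, but any
  arc determines the same plane. The full plate region is a thin slab
  around that plane (the true major-axis extremes sit on the rounded rim,
  not on the flat face), and three validity rules separate a real
  footplate from flat patches elsewhere on an incomplete stapes: the slab
  must reach millimetre scale along its major axis, fill that axis
  contiguously, and *bound* the solid (essentially every vertex on one
  side of its plane — the plate caps the bone). H and J are the extreme vertices along the in-plane principal
  axis (total-least-squares plane fit, 2D PCA; perforations cannot move
  the extremes because holes are interior; a near-isotropic projection is
  flagged ambiguous). G and I realize the *maximum* head-to-footplate
  distance — the literal reading of "total height" — via an exact
  two-region farthest pair; when the incus long-process tip is known, G
  instead snaps to the articular contact vertex.

**Anatomical parameterization.** Distances are Euclidean norms; the joint
angle at G uses the stable `atan2(|u × v|, u·v)` form; volumes are
divergence-theorem mesh volumes (voxel-count volumes are kept in the QC
block as a gross-error check). A stapes whose landmarks cannot be found
yields a flagged partial result — the four stapes-dependent fields are
`NA` with availability flags — never a pipeline failure, because incomplete
stapes segmentation is the common clinical failure mode.

## The phantom generator

No clinical volumes ship with the package, so every downstream stage is
validated on parametric phantoms: unions of spheres, capsules and
elliptical plates chosen so that *every* reported parameter has a
closed-form ground truth.

* Malleus: head sphere + neck/manubrium capsule anchored at the head
  centre + lateral-process stalk whose cap apex is exactly B. Given target
  AC, BC, AB the construction places C on the head-centre axis and solves
  the two-sphere intersection for B; all three distances are exact by
  construction.
* Incus: body sphere + two process capsules radiating from its centre; the
  inter-process angle is solved from (DG, EF, FG, body radius). D and E
  are exact sphere antipodes (the reason the body is a sphere rather than
  an ellipsoid: "farthest body point from an external point" has no closed
  form on a triaxial ellipsoid).
* Stapes: head sphere, two crura capsules, elliptical plate with optional
  through-hole (perforation) and obliquity (tilt about the minor axis).
  The head is offset slightly along the major axis so the farthest bottom
  corner — landmark I — is unique. HJ = 2a exactly; GI is calibrated
  through the head height.
* Chain: the stapes is articulated at the incus long-process tip with a
  0.12 mm joint gap and rotated so the ground-truth ∠DGI equals the
  requested angle exactly; the malleus sits laterally with 0.4 mm
  clearance. Label collisions beyond a tolerance are a placement error.

Anchoring capsules at sphere centres makes each sphere∩capsule overlap a
half napkin-ring plus a buried hemisphere — closed form — and the
capsule-capsule overlap lies inside the body sphere, so inclusion-exclusion
collapses. Malleus and incus volumes are therefore analytic (the tests
cross-check them against 0.025 mm quadrature); the stapes crura/plate
junction has no closed form, so its reference volume uses 0.02 mm
quadrature of the implicit solid.

Default dimensions are the cohort's automated population means (total
heights 7.91 / 6.56 / 3.25 mm, footplate 2.63 mm, joint angle 96.83°), so
phantoms live in the anatomically plausible regime. The randomized suite
draws each dimension from its reported population SD truncated at ±1.5 SD,
with two added consistency rules: draws must keep DG the dominant incus
extent by 0.3 mm ("total height" is by definition the maximal extent; an
independent draw violating it describes no real incus and makes the
farthest-pair definition of D/G ill-posed at mesh resolution), and the
malleus lateral process must stand at least 1.5 mm clear of the A-C chord
(a near-collinear A-B-C triple is anatomically degenerate and
indistinguishable from surface noise). Voxelization is centre-inclusion: a voxel is on iff its
centre is inside the union; the convergence tests confirm the voxel-count
volume approaches the analytic volume as spacing shrinks.

What the phantoms do *not* emulate: CT intensity physics, partial-volume
and beam-hardening effects, segmentation-network errors, surrounding
temporal-bone anatomy, and the true sculpted shapes of the ossicles
(phantom realism is dimensional, not morphological). Passing the recovery
suite therefore demonstrates the geometric correctness of the measurement
chain, not the performance of any segmentation front end on real scans.
The boundary-flip perturbation harness (`perturb_volume`) emulates
segmentation boundary noise only.

## Numerical choices and degenerate inputs

* Ties everywhere (farthest pairs, axis extremes, tip ordering) break
  lexicographically on (x, y, z) for bit-reproducibility.
* Grid nodes lying (numerically) on the iso level are handled by vertex
  snapping in the extractor: all incident edges share the node itself as
  their vertex and the collapsed micro-triangles drop out.
* Curvature thresholds (`min_gauss` 2.5 mm⁻², `planar_h` 0.5 mm⁻¹,
  `nms_radius` 0.4 mm, plate slab 0.25 mm, minimum lateral protrusion
  1.2 mm) are config-exposed defaults tuned on phantoms at 0.1 mm spacing.
* Shapiro-Wilk gates use α = 0.05; constant samples short-circuit to
  p = 1 with an exact-tie flag; probabilities are clipped at 1e-7 in the
  cross-entropy; the soft Dice uses an epsilon so empty-vs-empty is 0.
* The stapes footplate, 2.5 voxels thick at default spacing, is the
  resolution-limited worst case: in grid-aligned poses its reconstructed
  thickness quantizes to whole voxel layers (±20% of the plate share of
  stapes volume). Random orientations average this out; the canonical
  axis-aligned pose is the single worst case and is tested with a wider
  tolerance than the randomized suite.

## Statistics

The replicate-consistency and method-agreement coefficient is ICC(3,1) —
two-way mixed effects, consistency definition, single measure — computed
from the ANOVA decomposition; the model is tagged in the output because
the convention (below 0.4 poor, above 0.75 high) is tied to it. Paired
comparisons gate on Shapiro-Wilk of the differences (paired t vs Wilcoxon
signed-rank); independent comparisons gate per group and apply the Welch
correction when Levene's test rejects equal variances (t vs Mann-Whitney
U); three or more groups gate on per-group normality plus homogeneity
(one-way ANOVA vs Kruskal-Wallis, the k-group rank test). No
multiple-testing correction is applied by default, matching the reporting
convention of the tables this mirrors. Null-simulation tests hold each
gated procedure's type-I error within [0.035, 0.065] at α = 0.05 over
1000 seeded replicates.

## Problem sizes

The shipped validation uses 50 randomized chain phantoms at 0.1 mm
spacing for recovery (about 6-7 minutes on one core), 1000 replicates per
type-I simulation, and 200 subjects × 3 raters for the ICC recovery —
sizes at which the Monte-Carlo error is comfortably below every asserted
tolerance.

## A worked example

```{r example, eval = FALSE}
ph <- generate_chain_phantom(spacing = 0.1)   # analytic ground truth inside
res <- measure_chain(ph$volume)
tidy(res)
# compare to ph$truth$parameters / ph$truth$volumes
```

## Known limitations

* Landmark rules assume the gross topology of a normal chain; dysplastic
  ossicles (fused joints, absent processes) are rejected with named
  errors rather than measured.
* Mesh volumes inherit a small negative bias (about 1% for compact
  ossicles, up to ~5% for the thin-featured stapes) from the
  mask-to-surface chain at 0.1 mm; sub-voxel accuracy beyond that would
  need intensity data, which the pipeline deliberately does not use.
* The minimum bounding box is near-minimal, not provably minimal; the
  guarantee is "never worse than PCA, within 1% of a dense rotation grid
  on fixtures".
* The active-contour loss is implemented and validated as a standalone
  component; training a segmentation network with it is out of scope.
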