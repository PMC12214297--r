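# ossimetry

Automated 3D morphometry of the middle-ear ossicular chain from labeled
ultra-high-resolution CT volumes.

The ossicular chain — malleus, incus, stapes — conducts sound from the
eardrum to the inner ear, and reconstructive surgery needs its dimensions
preoperatively. Manual measurement on multiplanar CT views is slow and
operator-dependent. `ossimetry` takes a segmentation label volume (one
integer label per ossicle, isotropic ~0.1 mm grids) and computes the twelve
standard parameters automatically: eight distances between named landmarks
A–J (e.g. malleus total height *AC*, incus total height *DG*, stapes
footplate length *HJ*), the incudostapedial joint angle *∠DGI*, and the
three ossicle volumes.

The pipeline per ossicle:

1. **Surface reconstruction** — exact signed distance field from the mask,
   curvature-deviation subvoxel refinement with a hard half-voxel fidelity
   band, watertight iso-surfacing on a conforming tetrahedral cell
   decomposition, Hamming-windowed-sinc low-pass mesh smoothing.
2. **Feature point identification** — discrete Gaussian (angle-deficit) and
   mean (cotangent-Laplacian) curvature maps, protrusion-tip detection with
   non-maximum suppression, a deterministic near-minimal oriented bounding
   box, exact farthest-point pairs, and a PCA major-axis fit of the stapes
   footplate that is robust to perforations and oblique plates.
3. **Anatomical parameterization** — landmarks map to the twelve parameters;
   a stapes whose landmarks cannot be found yields a flagged partial result
   (the clinically common case), never a hard failure.

Because no clinical data ship with the package, it includes a parametric
**phantom generator**: ossicle-scale solids (unions of spheres, capsules and
elliptical plates) whose landmarks, distances, joint angle and (for
malleus/incus) volumes are known in closed form, sized by default to the
study cohort's population means. Every stage of the pipeline is validated
against these analytic ground truths, including degenerate stapes cases
(perforated or 20°-oblique footplates) and seeded boundary-noise
perturbations.

Also included: the **Euler-curve-energy active-contour loss**
(0.5·Dice + 0.5·CE + 1e-5·∫(α + β·κ²)dℓ with α = β = 0.1) as a standalone,
analytically tested component, and the study-style **statistics workflow**
(ICC(3,1) replicate consistency, normality-gated paired / two-group /
multi-group comparisons, chi-square goodness of fit, mean ± SD summary
tables).

## Worked example

```r
library(ossimetry)

ph  <- generate_chain_phantom(spacing = 0.1)  # labeled volume + ground truth
res <- measure_chain(ph$volume)
tidy(res)
#> # A tibble: 12 × 5
#>    ear_id parameter                 value available unit
#>  1 ear    malleus_total_height_AC    7.90 TRUE      mm
#>  2 ear    malleus_manubrium_BC       4.36 TRUE      mm
#>  3 ear    malleus_head_neck_AB       4.81 TRUE      mm
#>  4 ear    incus_total_height_DG      6.53 TRUE      mm
#>  5 ear    incus_total_width_EF       4.96 TRUE      mm
#>  6 ear    incus_process_distance_FG  5.55 TRUE      mm
#>  7 ear    stapes_total_height_GI     3.16 TRUE      mm
#>  8 ear    stapes_footplate_HJ        2.62 TRUE      mm
#>  9 ear    incudostapedial_angle_DGI 95.5  TRUE      deg
#> 10 ear    malleus_volume             9.11 TRUE      mm^3
#> 11 ear    incus_volume              12.0  TRUE      mm^3
#> 12 ear    stapes_volume              1.38 TRUE      mm^3
```

The phantom's analytic truth is `ph$truth`: here AC = 7.91, DG = 6.56,
GI = 3.25, HJ = 2.63 mm and ∠DGI = 96.83°, so every distance above is
recovered within two voxels (0.2 mm) and the angle within ~1.5°. The
randomized validation suite (`evaluate_recovery(50, seed = 1)`) repeats
this over 50 posed, size-jittered chains and reports per-parameter bias,
MAE and maximum error; `autoplot()` on the report draws the error
distributions.

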