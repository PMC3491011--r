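---
title: "Group-wise TBSS on synthetic FA phantoms: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-wise TBSS on synthetic FA phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What this package computes

Tract-based spatial statistics (TBSS) compares fractional anisotropy (FA)
between groups along the centres of white-matter tracts: FA maps are brought
into a common space, averaged, the average is thinned to a one-voxel-wide
*skeleton* of tract centres, each subject's local FA maximum is *projected*
onto the skeleton, and voxel-wise statistics with permutation-based
family-wise-error (FWE) control are run on the projected values. The quality
of the whole chain rests on the common-space registration step, and this
package implements and compares four ways of defining that common space:

* **ST** — every subject is registered directly (affine, then non-rigid) to
  a fixed standard-space template;
* **RS** — the *most representative subject* (the cohort member onto which
  all others need the least non-rigid deformation, found from pairwise
  registrations) becomes the bridgehead, and only an affine maps it onward
  to standard space;
* **SS** — a *study-specific template* (the voxel-wise mean of ST-aligned
  images) becomes a second-pass registration target for the original
  images;
* **GW** — an unbiased *group-wise atlas* built iteratively: register all
  subjects to the current atlas, re-average, repeat, with a coarse-to-fine
  schedule of one rigid, four affine and up to ten non-rigid iterations
  (the first iteration is rigid-only so the random choice of the initial
  atlas subject cannot bias the result); the converged atlas is affinely
  mapped to standard space.

Everything runs on synthetic FA phantoms with known ground truth, so
specificity (false positives under pure misalignment) and sensitivity
(detection of planted FA reductions) can be measured exactly.

## The phantom

`make_template()` builds a 48×48×48 voxel (2 mm isotropic) "brain": an
ellipsoidal support with background FA 0.11, three smoothly curved tubular
tracts with a Gaussian cross-profile (peak FA 0.70–0.80 at the centreline,
SD 2 voxels, labelled out to 2.2 SD where the profile has fallen below
0.2), a smooth axial taper at the tube ends, and a CSF-like ventricle
(FA 0.05) placed directly under the tract plane, as periventricular white
matter sits over the lateral ventricles. Stored centrelines are defined as
the per-cross-section FA argmax, so the "centreline voxel is the maximum of
its cross-section" property holds by construction. Key choices:

* **Tube width (SD 2 voxels = 4 mm).** Thin tubes make projected peak
  values fragile under millimetre-scale smoothing; 4 mm puts the phantom in
  the regime where the interpolation-matching kernel (below) perturbs peaks
  by a few hundredths of FA at most, comparable to real data.
* **Ventricle position.** Ventricular expansion is the dominant deformation
  of neurodegeneration; placing the ventricle adjacent to the tract plane
  makes that expansion actually displace tracts (about 2 mm at the
  centrelines for severity 0.6), which is the regime the specificity
  experiment stresses.
* **Noise.** Subjects receive additive Gaussian FA noise (default SD 0.05,
  clamped to [0, 1]), matching typical inter-subject FA variability at
  skeleton voxels; inter-individual anatomy is emulated by random smooth
  displacement fields (white noise smoothed at 8 mm, scaled to a 3 mm
  maximum).
* **Atrophy.** `simulate_atrophy()` uses an analytic radial expansion
  centred on the ventricle — displacement grows linearly inside the
  ventricle and decays exponentially outside with the effective ventricle
  radius as length scale, so `severity` is the fractional outward movement
  of the ventricle boundary. The forward field (positive divergence inside
  the ventricle) is returned alongside the numerically inverted pull-back
  field used for resampling. Severity 0.8 with a 3 mm random component is
  used as the "AD-like" default; the literature gives no millimetre value
  for typical atrophic deformation, so this is a package calibration, not a
  measured quantity.

What the phantoms do *not* emulate: crossing fibres, sheet-like tracts,
partial-volume gradients, intensity inhomogeneity, or anatomy complex
enough to defeat a well-regularised registration. Consequences of that last
point are discussed under *Known limitations*.

## Registration

All displacement fields are stored in pull-back convention (`out(x) =
in(x + u(x))`, `u` in mm on the fixed grid); composition, inversion
(fixed-point iteration, 50 iterations, 0.05 voxel tolerance) and
trilinear/nearest resampling operate on that convention. Linear
registration maximises normalised cross-correlation by a multi-resolution
derivative-free simplex search over rigid (6) or staged affine (12)
parameters; the returned transform is never worse than the identity under
NCC. Two deliberately distinct non-rigid algorithms share one contract:

* `pipeline` — parametric: a coarse control-point lattice (spacing 4 then
  2 voxels over a 2-level pyramid) trilinearly interpolated to a dense
  field, fitted to the SSD loss with normalised-force updates and monotone
  (backtracking) acceptance;
* `independent` — non-parametric demons: intensity-difference forces with
  Gaussian fluid (1.5 mm) and elastic (1 mm) regularisation over a 3-level
  pyramid.

The simulation experiments always deform data with `independent` and
register with `pipeline`, so the evaluation never lets the pipeline's
deformation model "see" data generated by itself.

## Skeletonisation and projection

The skeleton test is the classic centre-of-gravity rule: for each voxel
above the FA threshold (default 0.2), the FA-weighted centre of gravity of
the 3×3×3 neighbourhood estimates where the local tract mass lies;
off-centre voxels must carry more FA than both integer-voxel neighbours
along that direction, plateau centres must dominate their two
steepest-fall-off axes. Integer-voxel comparisons keep the test exact and
the skeleton one voxel thick; a cross-section uniqueness pass removes
shoulder voxels that have a stronger skeleton voxel in (approximately) the
same cross-section, and connected components below 5 voxels are pruned as
spurious isolated maxima. The tract-perpendicular frame for projection
comes from the local FA Hessian (eigenvectors of the two most negative
curvatures; the third is the tract tangent).

Projection scans, for each skeleton voxel, the grid voxels within
`max_search_mm` (default 8 mm) whose offset lies in the cross-sectional
slab (tangential component below ~0.6 voxel), again at integer offsets so
peak values are read exactly. The search is bounded by an exact
nearest-skeleton-voxel partition: a sample may be claimed while the
searching voxel is, to within one voxel, its nearest skeleton voxel. The
one-voxel slack matters for voxelised diagonal tracts, whose Voronoi cells
otherwise truncate the search a fraction of a voxel before the true ridge.

## Statistics

Projected matrices (subjects × skeleton voxels) are analysed with a
voxel-wise general linear model (intercept + group + optional nuisance
covariates); the group t-statistic feeds threshold-free cluster enhancement
(TFCE) with the standard parameters E = 0.5, H = 2, dh = max(stat)/100,
26-connectivity restricted to skeleton voxels. FWE control uses the
permutation distribution of the maximum enhanced statistic; when the group
sizes admit fewer distinct relabelings than requested permutations, all of
them are enumerated and p-values are exact proportions, otherwise the
add-one estimator `(1 + #{max >= obs})/(B + 1)` is used (so p-values never
fall below `1/(B+1)`). With nuisance covariates, Freedman–Lane residual
permutation is the default (`scheme = "labels"` gives raw label
permutation). Both one-sided contrasts are always computed and corrected
separately, as the reference permutation tool reports them; each map is
FWE-calibrated at its own level, which the null-calibration experiment
verifies per direction.

## The evaluation experiments

**Specificity.** Ten controls are warped (affine + demons) onto ten
atrophy-deformed targets; the originals are smoothed with the Gaussian
kernel (candidates 0.5/1/1.5/2 mm) that minimises the round-trip RMSE
between smoothed originals and inverse-warped warped controls. The pipeline
then compares smoothed originals with warped controls: both groups carry
identical anatomy, so any significant voxel is a false positive. The
headline per-tract counts use the *decrease* contrast (warped below
original), the direction in which misalignment manifests and the direction
the source experiments display. The increase contrast is reported
alongside: on these phantoms it carries a small uniform FA elevation in the
warped group (~0.04), because the round-trip criterion matches the kernel
to *two* resampling steps while the in-pipeline comparison differs by only
one, and because projection's maximum is taken over noisier (unsmoothed)
values in the warped group. That artifact is a property of the
interpolation-matching procedure on crisp phantoms, identical across
registration strategies, and therefore kept out of the strategy comparison.

**Sensitivity.** Tract labels are mapped onto each control by an affine +
non-rigid label warp (nearest neighbour), FA inside the masks is reduced by
10–40%, and the pipeline compares originals with reduced copies; a tract
counts as detected when at least one skeleton voxel inside its mask shows a
significant decrease. The significant-voxel count is reported as well,
since the minimal one-voxel rule is a convention.

**Diagnostics.** `groupwise_sd_map()` (voxel-wise SD across aligned
subjects), `cohort_variance()` (mean voxel-wise variance, the quantity
traced across group-wise iterations), and `bland_altman()` (per-entry mean
and difference of two projected matrices restricted to their skeleton
intersection) quantify alignment quality.

## Numerical and design choices

* Voxel coordinates are 1-based in R; world coordinates are
  `(index - 1) * voxel_size` mm. All grids in one analysis share a voxel
  size.
* The group-wise schedule is stateless per iteration (originals are
  re-registered to the current atlas each time; nothing in the iterative
  scheme requires incremental field composition, and stateless iterations
  cannot accumulate interpolation error). During non-rigid iterations the
  subject-to-atlas affine from the last affine iteration is reused and only
  the non-rigid part is refitted, since the atlas pose barely moves after
  the affine stage.
* Convergence: the schedule is fixed (1 rigid + 4 affine + 10 non-rigid)
  with an early stop once the variance improves by less than 0.1% between
  non-rigid iterations; a non-improving update is discarded rather than
  recorded, so the variance trace is monotone by construction and the
  returned atlas is the best one seen.
* RS pairwise registrations run at half resolution by default (the ranking,
  not the millimetre values, is consumed) and an optional `max_pairs` cap
  bounds the O(n²) cost; composite transforms to template space are always
  recomputed at full resolution. The representative is the subject onto
  which the others need the least recovered deformation — measured in the
  same direction as the transforms that are subsequently reused.
* Ties: representative selection takes the lowest index; skeleton
  local-maximum ties retain the voxel (weak inequality on the plus side,
  strict on the minus side); TFCE threshold grids use `h = i*dh` with a
  1e-12 tolerance so boundary voxels are never dropped by accumulated
  floating-point error.
* Test-scale defaults: 48³ grids, n = 10 + 10, 500 permutations. The
  conventional full-scale settings (5000 permutations, alpha 0.05,
  FA > 0.2) are the package defaults in `run_config()`.

## Known limitations

* The phantoms are geometrically simple; a well-regularised registration
  compensates atrophy-scale misalignment almost completely here, so the
  specificity experiment's strategy contrast is much weaker than on real
  data — all strategies, not only the group-wise atlas, reach zero
  decrease-direction false-positive tracts at the default severity. The
  experiment still verifies the ordering claim, but a zero-zero ordering
  says less than a three-zero one.
* Because the standard template *is* the generating anatomy, ST enjoys an
  on-grid advantage phantoms give it for free: its aligned tube peaks land
  exactly on grid voxels, while the group-wise atlas pose is fractionally
  offset from the template grid, costing its projected peaks ~0.01 FA of
  interpolation attenuation. The Bland–Altman median difference (GW − ST)
  is therefore slightly *negative* on phantoms (≈ −0.01) even though GW's
  skeleton-masked SD is lower; on real data, with broad FA ridges and a
  template that is not the generating anatomy, this artifact vanishes.
* FA scalars only: no tensor reorientation, no orientation-aware atlas
  construction, no diffusion-signal simulation.
* No diffeomorphic guarantees; fields are regularised but not
  velocity-integrated, and inversion is numerical.
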