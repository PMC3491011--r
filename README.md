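# gwtbss — group-wise tract-based spatial statistics on synthetic FA phantoms

Voxel-wise group comparison of white-matter fractional anisotropy (FA)
hinges on how FA maps are brought into a common space. `gwtbss` implements
the full TBSS (tract-based spatial statistics) chain —

```
register → mean FA → skeletonise (FA > 0.2) → project local maxima → permutation statistics
```

— behind four interchangeable common-space strategies, and ships a phantom
simulator with exact ground truth so that the specificity and sensitivity
of each strategy can be *measured* rather than assumed. It is aimed at
methods researchers studying how registration choices propagate into
skeleton-level statistics, particularly in atrophied (ventricle-expanded)
cohorts where standard template registration is most stressed.

The four strategies:

| strategy | common space |
|---|---|
| `st` | direct affine + non-rigid registration of every subject to a standard template |
| `rs` | the cohort member needing the least pairwise non-rigid deformation becomes the bridgehead; only an affine maps it to standard space |
| `ss` | subjects are re-registered to the mean of their own ST-aligned images |
| `gw` | an unbiased iterative group-wise atlas (1 rigid + 4 affine + up to 10 non-rigid register-all/re-average iterations, rigid first so the random initial subject cannot bias the atlas), affinely mapped to standard space |

Statistics on the projected skeleton values: general linear model
(intercept + group + optional nuisance covariates), threshold-free cluster
enhancement (TFCE, E = 0.5, H = 2, skeleton-restricted 26-connectivity),
and FWE correction by the permutation distribution of the maximum enhanced
statistic (exact enumeration whenever the group sizes allow it,
Freedman–Lane residual permutation under covariates).

## A worked example

```r
library(gwtbss)

tp   <- make_template(seed = 1)                      # 48^3 phantom, 3 tracts
ctrl <- make_cohort(tp, cohort_spec(10, seed = 21))  # 10 synthetic controls

# plant a 40% FA reduction inside every tract and ask the group-wise
# pipeline to find it
rep <- run_sensitivity(ctrl, tp$fa, tp$labels, fractions = 0.4,
                       strategy = "gw", n_perm = 500, seed = 13)
rep$per_tract[["0.4"]]
#>   tract n_skeleton_voxels n_significant_voxels   min_p_fwe significant
#> 1     1                28                   26 0.001996008        TRUE
#> 2     2                22                   22 0.001996008        TRUE
#> 3     3                25                   25 0.001996008        TRUE
```

Every tract is detected: nearly all skeleton voxels inside each planted
mask reach
the corrected significance floor `1/(B+1) = 1/501 ≈ 0.002` for the
FA-decrease contrast. On an undisturbed cohort the same pipeline returns no
voxel below `p_fwe = 0.05` (the null calibration in the test suite measures
the family-wise false-positive rate against its exact binomial band).

The atrophy phantom drives the specificity experiment:

```r
ad      <- make_cohort(tp, cohort_spec(10, seed = 22))
targets <- lapply(seq_along(ad), function(i)
  simulate_atrophy(ad[[i]]$fa, tp$ventricle, severity = 0.8,
                   seed = 100 + i, random_amplitude_mm = 3)$fa)
sc <- make_specificity_cohort(ctrl, targets)   # demons-warp + kernel match
sc$kernel_mm
#> [1] 1.5
rep_gw <- run_specificity(sc$smoothed_controls, sc$warped_controls, "gw",
                          tp$fa, tp$labels, n_perm = 500, seed = 7)
rep_gw$n_false_positive_tracts
#> [1] 0
```

Both groups carry identical anatomy, so any significant decrease is a false
positive; the group-wise atlas produces none.

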