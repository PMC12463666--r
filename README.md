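# surfmorph

Vertex-wise 3D morphometry of the abdominal subcutaneous adipose tissue
(ASAT) layer, for imaging scientists who want to move past "total fat
volume" to *where* the fat sits and what that distribution is associated
with.

The phenotype is a thickness field on a common template surface: for every
template vertex `v`, the Euclidean distance (mm) between the outer boundary
of the subcutaneous layer and the body-cavity surface. Stacked over subjects
it becomes an `n x V` matrix **T**, and the package provides the full chain
from binary segmentation volumes to three analyses of **T**:

* **Statistical parametric maps.** Per-vertex linear regression
  `T[, v] ~ covariates` (everything standardised, so coefficients are in SD
  units), spatially enhanced with threshold-free cluster enhancement

  `TFCE(v) = Σ_h e_v(h)^E · h^H · dh`  (E = 0.5, H = 2),

  tested with Freedman–Lane permutation of reduced-model residuals
  (`p_v = (1 + #{TFCE* ≥ TFCE}) / (n_perm + 1)`, one map per effect sign),
  and thresholded by Benjamini–Hochberg FDR. Summaries per covariate and
  sign: median β̂, IQR, and significance area (% of vertices).
* **Longitudinal maps.** Per-vertex random-intercept mixed models
  `y = Xβ + b_subject + ε` for two-visit data (REML by 1-D profiling of
  `σ_b²/σ²`), with visit × disease interaction and FDR over vertices.
* **Shape scores and risk.** Sparse PCA of **T** (median-centred,
  alternating regression with an L1 threshold; classical PCA at sparsity 0)
  gives localised shape modes; Cox proportional-hazards models compare
  `adjustments + 4 PC scores` against `adjustments + ASAT volume` by AIC and
  Harrell's c-index, with hazard ratios, 95% CIs and FDR-adjusted p values.

Geometry comes from an isosurface extractor (tetrahedral marching with
sub-voxel interpolation), umbrella Laplacian smoothing, multi-start ICP
template construction, closest-point template propagation, and exact
point-to-triangle thickness queries (compiled). A synthetic-cohort generator
with planted, spatially localised covariate effects provides exact ground
truth for every stage; study-scale quality-control rules (154 mm maximum
thickness exclusion; lipodystrophy from FMR > 1.2 in women / > 1.7 in men)
are implemented and tested against hand-computed decisions.

## Worked example

Plant a +0.5 SD visceral-fat effect on a cap covering 20% of the template,
simulate 200 subjects, and ask the SPM stage to find it:

```r
library(surfmorph)

spec <- cohort_spec(
  n_subjects = 200,
  effect_regions = list(
    effect_region(center_direction = c(1, 0, 0), angular_radius = acos(0.6),
                  covariate = "vat_l",
                  beta_mm_per_sd = beta_for_standardized_effect(cohort_spec(), 0.5))),
  seed = 42)

cohort <- generate_cohort(spec)   # template, covariates, thickness, ground truth
design <- design_matrix(cohort$covariates, c("age", "vat_l"))
spm    <- run_spm(cohort$thickness, design, spm_config(n_permutations = 500, seed = 42))
tidy(spm)
#> # A tibble: 4 × 8
#>   covariate sign     n_significant significance_area_pct median_beta_std
#> 1 age       positive             0                  0              NA
#> 2 age       negative             0                  0              NA
#> 3 vat_l     positive           462                 18.0             0.448
#> 4 vat_l     negative             0                  0              NA
#>   iqr_beta_std median_beta_mm iqr_beta_mm
#> 3       0.0369          0.668      0.0460
```

The null covariate (age) stays silent; the planted region is detected with
18.0% significance area (truth: 20% minus the tapered rim) and a median
standardised coefficient of 0.448 for a planted 0.5. Against the stored
ground-truth mask:

```r
gt  <- cohort$ground_truth$region_mask$vat_l
det <- spm$maps$vat_l$sig_pos
2 * sum(gt & det) / (sum(gt) + sum(det))
#> [1] 0.94        # Dice overlap
autoplot(spm, "vat_l")   # flattened beta map with the significant region outlined
```

Downstream, `fit_spca()` + `run_survival_study()` fit and compare the volume
and thickness-shape hazard models, and `run_longitudinal_map()` produces the
two-visit change maps; `run_pipeline(study_config(out_dir))` chains every
stage (simulate → mesh → register → thickness → spm → ssa → survival) with a
JSON manifest per stage. See the vignette
(`vignettes/asat-morphometry.Rmd`) for the models, parameter choices and the
validation design.

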