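---
title: "Vertex-wise morphometry of the subcutaneous adipose layer: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vertex-wise morphometry of the subcutaneous adipose layer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Abdominal subcutaneous adipose tissue (ASAT) is usually summarised as a single
volume, discarding where on the body the fat sits. This package implements a
surface-based alternative: the ASAT layer is represented as a *thickness field*
over a template surface — at every template vertex, the Euclidean distance (mm)
between the outer boundary of the subcutaneous layer and the body-cavity
surface — and that subjects-by-vertices matrix becomes the phenotype for three
analyses:

1. **Mass-univariate regression maps (SPM).** Per-vertex linear models of
   thickness on anthropometric covariates, spatially enhanced with
   threshold-free cluster enhancement (TFCE), tested by Freedman–Lane
   permutation, and thresholded with Benjamini–Hochberg FDR. Reported per
   covariate and per effect sign as the median coefficient, its IQR, and the
   *significance area* (percentage of vertices in the significant mask).
2. **Longitudinal maps.** Per-vertex random-intercept linear mixed models for
   two-visit data, with visit, disease, and visit-by-disease fixed effects,
   FDR over vertices, and visit effects reported as median mm change over the
   significant region by sign.
3. **Shape scores and risk.** Sparse principal component analysis of the
   thickness matrix gives localised shape modes; their subject scores enter a
   Cox proportional-hazards model that is compared — by AIC and Harrell's
   c-index — against a conventional model using total tissue volume.

# From segmentations to thickness fields

`extract_surface()` converts a binary mask into a closed triangle mesh by
tetrahedral decomposition of each voxel cell (six tetrahedra per cell, linear
interpolation of the iso-level crossing at 0.5). Binary occupancy produces
staircase surfaces whose area is overestimated by roughly a quarter, so the
field is pre-filtered with a separable 3-tap kernel before interpolation;
originally occupied voxels are clamped to the inside of the iso level, so
single-voxel-thick structures cannot be erased by the filter. With the filter,
the surface area of a radius-10 voxel sphere is accurate to about 0.5%.
Surfaces touching the grid boundary are zero-padded first; only the largest
edge-connected component is kept (segmentation speckle removal).
`crop_by_planes()` clears voxels on the negative side of explicit cutting
planes (for example, truncating arms) — landmark detection is out of scope and
planes are supplied by the caller.

`laplacian_smooth()` applies the uniform umbrella filter (default 10
iterations, step 0.5). These values are a conventional choice for removing
voxelisation artefacts; they are exposed in the configuration, and all tests
that depend on geometry use them explicitly.

**Template correspondence.** `build_template()` aligns subject meshes to a
reference by multi-start iterative closest point (identity plus the four
proper principal-axes alignments; the best pilot start gets the full budget)
and moves each reference vertex to the mean of its closest points across
subjects. The averaging pass uses *rigid* alignment so that the template is a
true mean shape (affine alignment would rescale every subject onto the
reference, collapsing the mean); `affine_align()` is available and is used
when projecting subjects into template space. `propagate_template()` then
records, for each template vertex, the exact closest point (face + barycentric
coordinates) on the subject surface and resamples the subject at template
topology, so vertex `v` denotes the same anatomical location in every subject.
A deliberate fidelity gap: the free-form non-rigid registration used by
large-cohort pipelines is replaced by closest-point projection, which achieves
the same fixed-topology correspondence contract for the star-shaped surfaces
this package targets but does not model large non-linear anatomical
deformation. Closest-point resampling is idempotent only to curvature
(chord-sagitta) order: re-resampling an already-resampled mesh moves vertices
by a second-order amount that vanishes under template refinement — the test
suite pins this behaviour down quantitatively.

**Thickness.** `compute_thickness()` takes the template-resampled outer
surface and the subject's inner (body-cavity) surface and returns, at each
outer vertex, the minimum Euclidean point-to-triangle distance to the inner
surface — an exact closest-point query against the triangle soup, not a
vertex-to-vertex approximation. A normal-ray variant is exposed
(`method = "normal"`) for sensitivity analyses; the closest-point definition
is the default because it matches the Euclidean-distance definition of the
phenotype and is robust to noisy normals.

**Quality control.** `qc_filter()` excludes a subject when its *maximum*
vertex thickness exceeds a threshold, supplied either as an absolute value
(the study default, 154 mm, the cohort's 99.9th thickness percentile) or as a
percentile of the per-subject maxima (linear-interpolation quantile). Whether
the outlier statistic should be the per-subject maximum or a pooled quantile
is not uniquely determined by the phenotype definition; the maximum is the
conservative choice and is the one implemented, with the percentile rule
exposed. `derive_lipodystrophy()` implements the fat-to-muscle-ratio rule with
strict sex-specific cut-offs (FMR > 1.2 for women, > 1.7 for men).

# The statistical engine

**Standardisation.** All continuous covariates and every response column are
z-scored (mean 0, SD 1, `n - 1` denominator) before regression; binary
indicators are left on their 0/1 scale. Coefficient maps are therefore in SD
units; the recorded centring/scaling parameters convert medians back to mm per
covariate unit for reporting.

**TFCE.** For a statistic map `s`,
`TFCE(v) = sum over h = dh, 2dh, ..., h_max of e_v(h)^E * h^H * dh`, where
`e_v(h)` is the extent of the supra-threshold connected component containing
`v`. Defaults are the canonical surface values `E = 0.5`, `H = 2` with
`n_steps = 100` integration steps (`dh = h_max / n_steps`); extent is vertex
count by default, with area-weighted extents (barycentric vertex areas) as an
option. The implementation is an incremental union-find sweep over descending
thresholds (compiled); the test suite checks it against an independent
brute-force loop over thresholds and components to 1e-9 on dozens of random
graphs, plus a 3-vertex worked example computed by hand.

**Permutation inference.** Negative and positive effects get separate
one-sided TFCE maps (the negative map enhances `-t`). For a covariate of
interest, the Freedman–Lane scheme is used: fit the nuisance-only model,
permute its residuals with a seeded generator, refit the full model on the
permuted response, and enhance the resulting t map. Per-vertex p values are
`(1 + #{permuted TFCE >= observed}) / (n_permutations + 1)`, bounded away from
zero by construction. Freedman–Lane is preferred over raw-response permutation
because it respects nuisance covariates. FDR is controlled per covariate and
per sign map with Benjamini–Hochberg (per-vertex permutation p values are
used, not max-statistic FWER, since the reporting convention is FDR). The
default permutation count is 500 at desk scale.

**Longitudinal engine.** The per-vertex model is
`y = X beta + b_subject + e` with a single random intercept. REML reduces to a
1-D profile over `rho = sigma_b^2 / sigma^2`; with subject-indicator random
effects, Woodbury turns every REML quantity into subject-aggregated sufficient
statistics, so one `rho` evaluation for *all* vertices is a handful of matrix
products. `run_longitudinal_map()` scans a shared grid of 161 ratios spanning
1e-4 to 1e4 (plus exactly 0), refines the per-vertex optimum by parabolic
interpolation in log-rho, and solves GLS per vertex at the estimate.
`fit_vertex_lmm()` is the exact single-vertex reference (bracketing grid +
`optimize()`); the tests show both agree with `lme4`/`lmerTest` REML to at
least 1e-4 on shared data. p values use the normal Wald reference rather than
a t approximation — at the two-visit cohort sizes this stage targets the
difference is negligible, and the tests that compare against `lmerTest` use
estimates and standard errors, not p values.

**Shape model.** `fit_spca()` centres the thickness matrix by the per-vertex
*median* (the robustness device; score winsorisation at 4 MADs is optional)
and extracts components by rank-1 alternating regression: power iterations
with an L1 soft-threshold on the loading vector, deflation between
components, unit-norm loadings with the largest-magnitude entry positive. At
`sparsity = 0` this is exactly classical PCA (the anchor the tests verify
against `svd()` to 1e-6); positive sparsity localises each mode on the
surface. Explained variance for sparse, non-orthogonal loadings uses the
QR-adjusted variance of the score matrix to avoid double counting. Scores are
defined as the centred matrix projected on the loadings, so `spca_transform()`
on the training data reproduces them exactly.

**Survival comparison.** `fit_cox()` standardises continuous covariates and
fits the Efron-tie-corrected partial likelihood via `survival::coxph`,
reporting hazard ratios with Wald 95% CIs, AIC (`2k - 2 logPL`) and Harrell's
c-index; an independent in-package evaluation of the Efron partial likelihood
(`cox_partial_loglik()`) serves as a grid-search oracle in the tests.
`run_survival_study()` fits the two competing models — adjustments + volume
versus adjustments + the first 4 (configurably 25) sparse-PC scores — applies
BH-FDR across each model's hazard-ratio p values, and declares AIC and
c-index winners. Total-muscle covariates are refused in the thickness model
(they are correlated with the PCs by construction). Fewer than 10 events per
covariate triggers a warning, not an error.

# The synthetic cohort: what it emulates and what it does not

`cohort_spec()` + `generate_cohort()`/`generate_subject_masks()` produce the
validation cohorts. Geometry is an inner ellipsoid ("body cavity", default
semi-axes 70/60/80 mm) wrapped by an outer surface at radial distance

`t_i(u) = base + sum_j beta_j z_ij bump_j(u) + b_i(u) + e_iv(u)`

clipped below at one voxel. `bump_j` is an angular plateau with raised-cosine
falloff (plateau to 85% of the angular radius by default — the taper is kept
narrow so that a "planted region" has an unambiguous area and the plateau
dominates medians); `z_ij` are covariates in declared-SD units; `b_i` is a
smooth between-subject field (default SD 2 mm) shared across visits — it is
what the random intercept estimates — and `e_iv` a per-visit measurement field
(default SD 1 mm), so the default variance ratio is the 4:1 used in the
recovery tests. Both noise fields are smooth over the sphere (a row-normalised
kernel basis over 24 fixed quasi-uniform directions), giving exactly unit
pointwise variance and realistic spatial correlation. Covariate defaults
(age ~ N(60, 7.5), height ~ N(170, 9), grip strength ~ N(30, 10),
VAT ~ N(4, 1.8) litres, lognormal FMR, binary sex/T2D/hypertension with
prevalences 0.5/0.08/0.3) are in plausible population ranges; the
lipodystrophy indicator is derived from FMR and sex with the same rule the
analysis uses. Survival outcomes are exponential with rate
`baseline * exp(sum log_hr * score)` and administrative censoring.

Because shapes are ellipsoids with *analytic* radial thickness, the generator
doubles as an exact oracle: the measured mask-to-mesh-to-thickness value at a
vertex direction must match `analytic_thickness()` to within voxel
discretisation, and the tests enforce this. Two generation routes exist by
design: `generate_subject_masks()` exercises the full voxel → mesh →
correspondence → thickness chain and is validated end-to-end at small n;
`generate_cohort()` evaluates the same analytic model directly at template
vertices and is the fast path for cohort-scale statistical studies (n = 200,
~2,500 vertices), where re-running voxelisation and registration per subject
would add hours of compute and no information beyond what the oracle
equivalence test already establishes.

What the generator does **not** emulate: human body geometry (no limbs, no
non-star-shaped folds), MRI intensities or segmentation errors, missing data,
informative censoring, and non-linear covariate effects. Passing tests
therefore demonstrate that the estimators recover what they claim from data
satisfying their assumptions — not that a real cohort satisfies those
assumptions.

# Problem sizes, numerical choices and defaults

* Desk scale: template icosphere subdivision 4 (2,562 vertices), n = 200
  subjects, 500 permutations, 20 calibration replicates; the voxel route runs
  at 40–64 cubed grids with 4–6.6 mm spacing. These sizes were chosen so the
  whole validation suite runs on a laptop-class single core in minutes while
  keeping Monte-Carlo error far below the test tolerances.
* The planted "+0.5 SD" regional effect is constructed by inverting the
  standardisation: `beta_mm = beta_std * sqrt(s2 / (1 - beta_std^2))` with
  `s2` the total noise variance (`beta_for_standardized_effect()`), so the
  target standardised coefficient is a derived quantity, not a tuned one.
* The survival model-comparison study uses a *sparse* shape basis
  (soft-threshold 30 on the desk-scale matrix, localised loadings). With dense
  (sparsity-0) loadings the first four PCs span the volume direction almost
  perfectly (R² ≈ 0.997), making the volume-hazard condition's AIC comparison
  a near-tie decided by the parameter penalty; localised modes are both what
  the sparse decomposition is for and what gives the comparison its meaning.
* ICP: 50 iterations max, stop at objective improvement < 1e-8 mm²,
  deterministic subsampling of correspondences (1,500 moving, 4,000 fixed
  points) for cost control; Kabsch SVD solves each rigid step in closed form.
* Perfect-fit vertices (zero residual variance) produce large finite t values
  (capped) instead of infinities; permutation p values are floored at
  `1/(n_perm + 1)`; BH is applied per sign map.
* Degenerate inputs error early with informative messages: empty masks,
  rank-deficient designs (collinear columns are named), single-visit-only
  cohorts (random intercept unidentifiable), eventless survival tables,
  separation in Cox fits, mismatched templates.
* All randomness is seeded: the cohort spec carries one seed from which every
  subject-level draw derives; `spm_config()` seeds the permutation stream;
  RNG state is saved and restored around every internal draw, so package calls
  never perturb the caller's stream. Identical configuration and seed
  reproduce every artifact byte for byte; each pipeline stage writes a JSON
  manifest with the configuration hash.

# Known limitations

* Closest-point correspondence assumes approximately star-shaped surfaces; it
  will fold on strongly concave anatomy, and no non-rigid deformation model
  is provided.
* The per-vertex LMM fits a random intercept only — no random slopes, no
  more than two visits, and complete cases only (missing covariate cells are
  a hard error everywhere; no imputation is offered by design).
* Proportional hazards is assumed, not tested; competing risks and
  time-varying covariates are out of scope.
* TFCE p values are per-vertex with FDR control; familywise-error control via
  the max statistic is not implemented.
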