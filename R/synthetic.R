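#' Specify a synthetic morphometry cohort
#'
#' The generator emulates the data structure of an abdominal adipose-tissue
#' morphometry study: per subject, a pair of nested closed surfaces (an
#' inner "body cavity" ellipsoid and an outer surface offset from it by a
#' spatially varying radial thickness), voxelised onto a grid with physical
#' spacing. The radial thickness carries the planted signal:
#'
#' `t_i(u) = base + sum_j beta_j * z_ij * bump_j(u) + b_i(u) + e_iv(u)`
#'
#' where `u` is a unit direction, `bump_j` is an angular plateau with
#' raised-cosine falloff around a region centre, `z_ij` is subject i's
#' covariate j in declared-SD units (raw value for binary covariates),
#' `b_i(u)` is a smooth between-subject field with pointwise SD
#' `noise_sd_mm` shared across visits, and `e_iv(u)` a per-visit smooth
#' measurement field with pointwise SD `measurement_sd_mm`. Thickness is
#' clipped below at one voxel so the shell never vanishes. Because shapes
#' are ellipsoids with analytic radial thickness, the generator doubles as
#' an exact oracle for every downstream stage.
#'
#' @param n_subjects Number of subjects.
#' @param grid_shape Voxel grid dimensions (3 positive integers).
#' @param voxel_spacing_mm Voxel spacing (mm).
#' @param inner_radii_mm Semi-axes of the inner ellipsoid (mm).
#' @param base_thickness_mm Baseline shell thickness (mm).
#' @param effect_regions List of [effect_region()] entries.
#' @param covariates Named list of covariate declarations, each
#'   `list(dist = "normal", mean =, sd =)`, `list(dist = "bernoulli",
#'   prev =)` or `list(dist = "constant", value =)`.
#' @param noise_sd_mm Between-subject field SD (mm), shared across visits.
#' @param measurement_sd_mm Per-visit measurement field SD (mm).
#' @param visit2 Optional second-visit spec: `list(regions = list(list(
#'   center_direction, angular_radius, offset_mm, interaction = NULL)))`;
#'   `interaction` names a binary covariate restricting the offset to that
#'   subgroup (a visit-by-disease interaction).
#' @param survival Optional proportional-hazards spec: `list(baseline_hazard,
#'   log_hr (named by score column), censor_time)`.
#' @param seed Integer seed; identical spec + seed gives bitwise-identical
#'   output.
#' @return A validated `cohort_spec` object.
#' @export
cohort_spec <- function(n_subjects = 200L,
                        grid_shape = c(64L, 64L, 64L),
                        voxel_spacing_mm = c(4, 4, 4),
                        inner_radii_mm = c(70, 60, 80),
                        base_thickness_mm = 25,
                        effect_regions = list(),
                        covariates = default_covariates(),
                        noise_sd_mm = 2,
                        measurement_sd_mm = 1,
                        visit2 = NULL,
                        survival = NULL,
                        seed = 1L) {
  stopifnot(n_subjects >= 1, length(grid_shape) == 3, all(grid_shape > 0),
            length(voxel_spacing_mm) == 3, all(voxel_spacing_mm > 0),
            length(inner_radii_mm) == 3, all(inner_radii_mm > 0),
            base_thickness_mm > 0, noise_sd_mm >= 0, measurement_sd_mm >= 0)
  for (r in effect_regions) {
    if (!inherits(r, "effect_region")) abort("effect_regions must be built with effect_region()")
    if (!r$covariate %in% names(covariates))
      abort(sprintf("effect region references undeclared covariate '%s'", r$covariate))
  }
  if (!is.null(survival) && survival$baseline_hazard < 0)
    abort("baseline hazard must be non-negative")
  spec <- structure(list(
    n_subjects = as.integer(n_subjects), grid_shape = as.integer(grid_shape),
    voxel_spacing_mm = voxel_spacing_mm, inner_radii_mm = inner_radii_mm,
    base_thickness_mm = base_thickness_mm, effect_regions = effect_regions,
    covariates = covariates, noise_sd_mm = noise_sd_mm,
    measurement_sd_mm = measurement_sd_mm, visit2 = visit2,
    survival = survival, seed = as.integer(seed)), class = "cohort_spec")
  # containment: worst-case outer radius must fit strictly inside the grid
  max_beta <- if (length(effect_regions))
    sum(vapply(effect_regions, function(r) abs(r$beta_mm_per_sd), numeric(1))) else 0
  worst <- max(inner_radii_mm) + base_thickness_mm + 4 * max_beta +
    4 * (noise_sd_mm + measurement_sd_mm)
  half_extent <- min((grid_shape - 1) * voxel_spacing_mm) / 2
  if (worst >= half_extent)
    abort(sprintf(
      "shell does not fit in grid: worst-case radius %.1f mm >= half extent %.1f mm",
      worst, half_extent))
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> n=%d, grid %s @ %s mm, inner radii (%s) mm, base %.1f mm, %d effect region(s)\n",
    x$n_subjects, paste(x$grid_shape, collapse = "x"),
    paste(x$voxel_spacing_mm, collapse = "x"),
    paste(x$inner_radii_mm, collapse = ", "),
    x$base_thickness_mm, length(x$effect_regions)))
  invisible(x)
}

#' Declare a spatially localised covariate effect
#'
#' The angular bump is 1 inside `taper * angular_radius` of the centre
#' direction and falls to 0 with a raised-cosine profile at
#' `angular_radius`; outside the region the true effect is exactly zero.
#'
#' @param center_direction Unit 3-vector (normalised internally).
#' @param angular_radius Angular radius in radians, in (0, pi).
#' @param covariate Declared covariate name the effect attaches to.
#' @param beta_mm_per_sd Effect size: mm of thickness per declared SD of the
#'   covariate (per unit for binary covariates).
#' @param taper Fraction of the radius where the plateau ends.
#' @export
effect_region <- function(center_direction, angular_radius, covariate,
                          beta_mm_per_sd, taper = 0.85) {
  stopifnot(length(center_direction) == 3, angular_radius > 0,
            angular_radius < pi, taper > 0, taper <= 1)
  structure(list(
    center_direction = center_direction / sqrt(sum(center_direction^2)),
    angular_radius = angular_radius, covariate = covariate,
    beta_mm_per_sd = beta_mm_per_sd, taper = taper),
    class = "effect_region")
}

#' Default covariate declarations for the synthetic cohort
#'
#' Continuous anthropometric covariates (age, height, hand-grip strength,
#' visceral-fat volume, fat-to-muscle ratio) are Gaussian with recorded
#' means/SDs; binary indicators (male sex, type-2 diabetes, hypertension)
#' are Bernoulli with stated prevalence.
#' @export
default_covariates <- function() {
  list(age = list(dist = "normal", mean = 60, sd = 7.5),
       height = list(dist = "normal", mean = 170, sd = 9),
       hgs = list(dist = "normal", mean = 30, sd = 10),
       vat_l = list(dist = "normal", mean = 4, sd = 1.8),
       fmr = list(dist = "lognormal", meanlog = log(1.05), sdlog = 0.3),
       sex_m = list(dist = "bernoulli", prev = 0.5),
       t2d = list(dist = "bernoulli", prev = 0.08),
       hypertension = list(dist = "bernoulli", prev = 0.3))
}

# quasi-uniform directions on the sphere (golden-angle spiral); deterministic
fibonacci_directions <- function(m) {
  i <- seq_len(m) - 0.5
  phi <- acos(1 - 2 * i / m)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# smooth angular noise basis at directions U; rows L2-normalised so
# coefficients a ~ N(0, I) give pointwise variance exactly 1
noise_basis <- function(U, m = 24L, width = 0.2) {
  D <- fibonacci_directions(m)
  B <- exp((U %*% t(D) - 1) / width)
  B / sqrt(rowSums(B^2))
}

bump_profile <- function(cosang, angular_radius, taper) {
  ang <- acos(pmin(1, pmax(-1, cosang)))
  inner <- taper * angular_radius
  out <- numeric(length(ang))
  out[ang <= inner] <- 1
  sel <- ang > inner & ang < angular_radius
  out[sel] <- 0.5 * (1 + cos(pi * (ang[sel] - inner) / (angular_radius - inner)))
  out
}

# radial distance to the ellipsoid surface along unit direction u
ellipsoid_radius <- function(U, radii) {
  1 / sqrt((U[, 1] / radii[1])^2 + (U[, 2] / radii[2])^2 + (U[, 3] / radii[3])^2)
}

# all subject-level random draws, derived once from the spec seed
cohort_latents <- function(spec) {
  n <- spec$n_subjects
  m <- 24L
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  draws <- lapply(spec$covariates, function(cv) {
    switch(cv$dist,
           normal = rnorm(n, cv$mean, cv$sd),
           lognormal = stats::rlnorm(n, cv$meanlog, cv$sdlog),
           bernoulli = rbinom(n, 1, cv$prev),
           constant = rep(cv$value, n),
           abort(sprintf("unknown covariate distribution '%s'", cv$dist)))
  })
  A_between <- matrix(rnorm(n * m), n, m)
  A_visit1 <- matrix(rnorm(n * m), n, m)
  A_visit2 <- matrix(rnorm(n * m), n, m)
  covars <- tibble::as_tibble(draws)
  covars <- dplyr::mutate(covars,
    subject_id = sprintf("S%04d", seq_len(n)), .before = 1)
  list(covariates = covars, A_between = A_between,
       A_visit1 = A_visit1, A_visit2 = A_visit2)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# covariate value in effect units: declared z-score for continuous, raw for
# binary/constant
covariate_effect_units <- function(spec, covars, name) {
  cv <- spec$covariates[[name]]
  if (is.null(cv)) abort(sprintf("undeclared covariate '%s'", name))
  x <- covars[[name]]
  switch(cv$dist,
         normal = (x - cv$mean) / cv$sd,
         lognormal = (log(x) - cv$meanlog) / cv$sdlog,
         x)
}

#' Analytic radial thickness at unit directions (ground-truth oracle)
#'
#' Evaluates the generator's thickness model exactly at arbitrary
#' directions. With `include_noise = FALSE` this is the noiseless planted
#' signal, the oracle every mesh-measured thickness is checked against.
#'
#' @param spec A [cohort_spec()].
#' @param U Matrix of unit directions (rows).
#' @param subject_index Subject (1-based).
#' @param visit 1 or 2.
#' @param include_noise Add the subject and measurement noise fields.
#' @param latents Pre-computed cohort latents (internal reuse).
#' @return Numeric vector of thickness (mm), clipped below at one voxel.
#' @export
analytic_thickness <- function(spec, U, subject_index, visit = 1L,
                               include_noise = TRUE, latents = NULL) {
  if (subject_index > spec$n_subjects) abort("subject_index out of range")
  if (is.null(latents)) latents <- cohort_latents(spec)
  t <- rep(spec$base_thickness_mm, nrow(U))
  for (r in spec$effect_regions) {
    z <- covariate_effect_units(spec, latents$covariates, r$covariate)[subject_index]
    t <- t + r$beta_mm_per_sd * z *
      bump_profile(U %*% r$center_direction, r$angular_radius, r$taper)
  }
  if (visit == 2L && !is.null(spec$visit2)) {
    for (vr in spec$visit2$regions) {
      gate <- 1
      if (!is.null(vr$interaction))
        gate <- covariate_effect_units(spec, latents$covariates, vr$interaction)[subject_index]
      cd <- vr$center_direction / sqrt(sum(vr$center_direction^2))
      t <- t + vr$offset_mm * gate *
        bump_profile(U %*% cd, vr$angular_radius, vr$taper %||% 0.85)
    }
  }
  if (include_noise) {
    B <- noise_basis(U)
    a <- latents$A_between[subject_index, ]
    e <- if (visit == 1L) latents$A_visit1[subject_index, ] else latents$A_visit2[subject_index, ]
    t <- t + spec$noise_sd_mm * as.numeric(B %*% a) +
      spec$measurement_sd_mm * as.numeric(B %*% e)
  }
  pmax(t, max(spec$voxel_spacing_mm))
}

#' Generate the paired segmentation masks for one subject
#'
#' Voxelises the inner ellipsoid and the outer surface (inner radius plus
#' radial thickness) onto the spec's grid. The inner mask is strictly
#' contained in the outer mask by construction.
#'
#' @inheritParams analytic_thickness
#' @return List with `outer` and `inner` [voxel_mask()] objects.
#' @export
generate_subject_masks <- function(spec, subject_index, visit = 1L,
                                   latents = NULL) {
  if (subject_index > spec$n_subjects) abort("subject_index out of range")
  if (is.null(latents)) latents <- cohort_latents(spec)
  d <- spec$grid_shape
  sp <- spec$voxel_spacing_mm
  center <- (d - 1) / 2 * sp
  gx <- (seq_len(d[1]) - 1) * sp[1] - center[1]
  gy <- (seq_len(d[2]) - 1) * sp[2] - center[2]
  gz <- (seq_len(d[3]) - 1) * sp[3] - center[3]
  X <- array(gx, d)
  Y <- array(rep(gy, each = d[1]), d)
  Z <- array(rep(gz, each = d[1] * d[2]), d)
  R <- sqrt(X^2 + Y^2 + Z^2)
  U <- cbind(as.numeric(X), as.numeric(Y), as.numeric(Z)) / pmax(as.numeric(R), 1e-12)
  r_in <- ellipsoid_radius(U, spec$inner_radii_mm)
  thick <- analytic_thickness(spec, U, subject_index, visit = visit,
                              include_noise = TRUE, latents = latents)
  inner <- array(as.numeric(R) <= r_in, d) * 1L
  outer <- array(as.numeric(R) <= r_in + thick, d) * 1L
  list(outer = voxel_mask(outer, sp, origin_mm = -center),
       inner = voxel_mask(inner, sp, origin_mm = -center))
}

#' Draw the subject covariate table
#'
#' Continuous covariates from their declared Gaussian distributions, binary
#' indicators with their declared prevalence; a `lipodystrophy` column is
#' derived from `fmr` and `sex_m` with the sex-specific FMR rule when both
#' are declared. Identical spec + seed reproduces the table exactly.
#'
#' @param spec A [cohort_spec()].
#' @return Tibble with `subject_id` and one column per covariate; declared
#'   parameters are attached as the `"declared"` attribute.
#' @export
generate_covariates <- function(spec) {
  covars <- cohort_latents(spec)$covariates
  if (all(c("fmr", "sex_m") %in% names(covars))) {
    covars$lipodystrophy <- as.integer(
      derive_lipodystrophy(covars$fmr, ifelse(covars$sex_m == 1, "M", "F")))
  }
  attr(covars, "declared") <- spec$covariates
  covars
}

#' Generate proportional-hazards survival outcomes from shape scores
#'
#' Event times are exponential with subject rate
#' `baseline_hazard * exp(sum(log_hr * score))`, administratively censored
#' at `censor_time`.
#'
#' @param spec A [cohort_spec()] with a `survival` component.
#' @param scores Data frame or matrix of per-subject score columns named as
#'   in `spec$survival$log_hr`.
#' @return Tibble: `subject_id`, `time`, `event` (1 = event, 0 = censored).
#' @export
generate_survival <- function(spec, scores) {
  sv <- spec$survival
  if (is.null(sv)) abort("spec has no survival component")
  if (sv$baseline_hazard < 0) abort("baseline hazard must be non-negative")
  scores <- as.data.frame(scores)
  lp <- rep(0, nrow(scores))
  for (nm in names(sv$log_hr)) {
    if (!nm %in% names(scores)) abort(sprintf("score column '%s' missing", nm))
    lp <- lp + sv$log_hr[[nm]] * scores[[nm]]
  }
  rate <- sv$baseline_hazard * exp(lp)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed + 7919L)
  raw <- rexp(length(rate), rate = pmax(rate, 1e-300))
  time <- pmin(raw, sv$censor_time)
  tibble::tibble(subject_id = sprintf("S%04d", seq_along(rate)),
                 time = time,
                 event = as.integer(raw <= sv$censor_time))
}

#' Generate a full desk-scale cohort on a template sphere mesh
#'
#' The fast path for cohort-scale studies: evaluates the analytic radial
#' thickness model directly at the template vertex directions (the same
#' quantity the voxel-to-mesh pipeline measures, which is what makes the
#' generator an exact oracle), producing the per-visit thickness matrices,
#' covariate table and ground-truth maps in one call.
#'
#' @param spec A [cohort_spec()].
#' @param template_subdivisions Icosphere subdivision level for the template
#'   (4 gives 2562 vertices).
#' @return List: `template` (mean-shape [surface_mesh()]), `directions`,
#'   `covariates`, `thickness` (visit-1 [cohort_matrix()]), `thickness_visit2`
#'   (or NULL), and `ground_truth` (per-covariate true beta-mm maps, region
#'   masks, true visit-offset map).
#' @export
generate_cohort <- function(spec, template_subdivisions = 4L) {
  latents <- cohort_latents(spec)
  sph <- icosphere(template_subdivisions, radius = 1)
  U <- sph$vertices / sqrt(rowSums(sph$vertices^2))
  r_mean <- ellipsoid_radius(U, spec$inner_radii_mm) + spec$base_thickness_mm
  template <- surface_mesh(U * r_mean, sph$faces, clean = FALSE)
  n <- spec$n_subjects
  Y1 <- matrix(0, n, nrow(U))
  for (i in seq_len(n))
    Y1[i, ] <- analytic_thickness(spec, U, i, visit = 1L, latents = latents)
  ids <- latents$covariates$subject_id
  Y2 <- NULL
  if (!is.null(spec$visit2)) {
    Y2 <- matrix(0, n, nrow(U))
    for (i in seq_len(n))
      Y2[i, ] <- analytic_thickness(spec, U, i, visit = 2L, latents = latents)
    Y2 <- cohort_matrix(Y2, ids, template)
  }
  gt_beta <- list(); gt_mask <- list()
  for (r in spec$effect_regions) {
    b <- r$beta_mm_per_sd * bump_profile(U %*% r$center_direction,
                                         r$angular_radius, r$taper)
    gt_beta[[r$covariate]] <- (gt_beta[[r$covariate]] %||% 0) + b
    gt_mask[[r$covariate]] <- (gt_mask[[r$covariate]] %||% FALSE) |
      (as.numeric(bump_profile(U %*% r$center_direction, r$angular_radius, r$taper)) > 0)
  }
  visit_offset <- numeric(nrow(U))
  if (!is.null(spec$visit2)) {
    for (vr in spec$visit2$regions) {
      if (!is.null(vr$interaction)) next
      cd <- vr$center_direction / sqrt(sum(vr$center_direction^2))
      visit_offset <- visit_offset +
        vr$offset_mm * bump_profile(U %*% cd, vr$angular_radius, vr$taper %||% 0.85)
    }
  }
  list(template = template, directions = U,
       covariates = generate_covariates(spec),
       thickness = cohort_matrix(Y1, ids, template),
       thickness_visit2 = Y2,
       ground_truth = list(beta_mm = gt_beta, region_mask = gt_mask,
                           visit_offset_mm = visit_offset))
}

#' Effect size (mm) that yields a target standardised coefficient
#'
#' With per-vertex response SD `sqrt(beta^2 + s2)` at plateau vertices
#' (`s2` the total noise variance), the standardised coefficient is
#' `beta / sqrt(beta^2 + s2)`; inverting gives the mm effect to plant for a
#' desired standardised effect.
#'
#' @param spec A [cohort_spec()].
#' @param beta_std Target standardised coefficient in (0, 1).
#' @return Effect size in mm per SD.
#' @export
beta_for_standardized_effect <- function(spec, beta_std) {
  stopifnot(beta_std > 0, beta_std < 1)
  s2 <- spec$noise_sd_mm^2 + spec$measurement_sd_mm^2
  beta_std * sqrt(s2 / (1 - beta_std^2))
}
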