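#' Study configuration for the end-to-end pipeline
#'
#' One nested configuration object drives [run_pipeline()]: the synthetic
#' cohort spec, geometry options (smoothing), template construction size,
#' QC threshold, SPM / SPCA / survival options and the global seed. The
#' configuration hash is stamped into every stage manifest, so any
#' parameter change (e.g. a TFCE exponent) changes every downstream hash.
#'
#' @param out_dir Output directory for stage artifacts.
#' @param spec A [cohort_spec()]; its seed is the global seed.
#' @param smooth_iterations,smooth_lambda Laplacian smoothing parameters.
#' @param template_subjects Number of subjects used to build the template.
#' @param qc_max_thickness_mm QC exclusion threshold (mm).
#' @param spm An [spm_config()].
#' @param spca_k,spca_sparsity Shape-model options.
#' @param survival_adjustment Adjustment covariates for the survival stage.
#' @return A `study_config` list with a `hash` field.
#' @export
study_config <- function(out_dir,
                         spec = cohort_spec(n_subjects = 16L,
                                            grid_shape = c(48L, 48L, 48L),
                                            voxel_spacing_mm = c(5.5, 5.5, 5.5)),
                         smooth_iterations = 10L, smooth_lambda = 0.5,
                         template_subjects = 5L,
                         qc_max_thickness_mm = 154,
                         spm = spm_config(n_permutations = 100L, seed = spec$seed),
                         spca_k = 2L, spca_sparsity = 0,
                         survival_adjustment = "age") {
  cfg <- list(out_dir = out_dir, spec = spec,
              smooth_iterations = smooth_iterations,
              smooth_lambda = smooth_lambda,
              template_subjects = min(template_subjects, spec$n_subjects),
              qc_max_thickness_mm = qc_max_thickness_mm,
              spm = spm, spca_k = spca_k, spca_sparsity = spca_sparsity,
              survival_adjustment = survival_adjustment,
              seed = spec$seed)
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "study_config")
}

#' Hash of a study configuration
#' @param config A `study_config` (the `out_dir` and any previous hash are
#'   excluded so the hash identifies the scientific parameters only).
#' @return Character md5 digest.
#' @export
config_hash <- function(config) {
  c2 <- unclass(config)
  c2$out_dir <- NULL
  c2$hash <- NULL
  digest::digest(c2, algo = "md5")
}

stage_manifest <- function(config, stage, inputs, outputs, t0, counts = list()) {
  man <- list(stage = stage,
              config_hash = config$hash,
              seed = config$seed,
              inputs = lapply(inputs, function(p)
                list(path = p, md5 = unname(tools::md5sum(p)))),
              outputs = outputs,
              counts = counts,
              elapsed_s = round(as.numeric(Sys.time()) - t0, 3))
  path <- file.path(config$out_dir, sprintf("manifest_%s.json", stage))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

require_artifacts <- function(config, paths, stage) {
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    abort(sprintf("stage '%s' is missing required artifact(s): %s",
                  stage, paste(missing, collapse = ", ")))
}

#' Run the morphometry pipeline end to end
#'
#' Executes the requested stages in order on the configuration's synthetic
#' cohort, writing versioned artifacts plus a JSON manifest (config hash,
#' seed, input hashes, record counts) per stage. Stage dependencies are
#' checked up front; deterministic stages are byte-identical across reruns
#' with the same configuration and seed.
#'
#' Stages: `simulate` (masks + covariate CSV), `mesh` (extract + smooth),
#' `register` (template + propagation), `thickness` (per-vertex thickness,
#' QC, cohort matrix), `spm`, `ssa`, `survival`.
#'
#' @param config A [study_config()].
#' @param stages Subset of the stage names above (default: all).
#' @return Invisibly, a named list of per-stage outputs.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "mesh", "register",
                                    "thickness", "spm", "ssa", "survival")) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- config$spec
  n <- spec$n_subjects
  out <- list()
  mask_path <- function(i, side) file.path(config$out_dir, sprintf("sub%03d_%s.nii.gz", i, side))
  mesh_path <- function(i, side) file.path(config$out_dir, sprintf("sub%03d_%s.ply", i, side))
  res_path <- function(i) file.path(config$out_dir, sprintf("sub%03d_resampled.ply", i))

  if ("simulate" %in% stages) {
    t0 <- as.numeric(Sys.time())
    latents <- cohort_latents(spec)
    for (i in seq_len(n)) {
      mk <- generate_subject_masks(spec, i, latents = latents)
      write_mask(mk$outer, mask_path(i, "outer"))
      write_mask(mk$inner, mask_path(i, "inner"))
    }
    cov_path <- file.path(config$out_dir, "covariates.csv")
    write_table(generate_covariates(spec), cov_path)
    outs <- c(vapply(seq_len(n), mask_path, "", side = "outer"),
              vapply(seq_len(n), mask_path, "", side = "inner"), cov_path)
    stage_manifest(config, "simulate", character(), outs, t0,
                   counts = list(n_subjects = n))
    out$simulate <- outs
  }

  if ("mesh" %in% stages) {
    t0 <- as.numeric(Sys.time())
    ins <- c(vapply(seq_len(n), mask_path, "", side = "outer"),
             vapply(seq_len(n), mask_path, "", side = "inner"))
    require_artifacts(config, ins, "mesh")
    for (i in seq_len(n)) {
      for (side in c("outer", "inner")) {
        m <- extract_surface(read_mask(mask_path(i, side)))
        m <- laplacian_smooth(m, config$smooth_iterations, config$smooth_lambda)
        write_mesh(m, mesh_path(i, side))
      }
    }
    outs <- c(vapply(seq_len(n), mesh_path, "", side = "outer"),
              vapply(seq_len(n), mesh_path, "", side = "inner"))
    stage_manifest(config, "mesh", ins, outs, t0)
    out$mesh <- outs
  }

  if ("register" %in% stages) {
    t0 <- as.numeric(Sys.time())
    ins <- vapply(seq_len(n), mesh_path, "", side = "outer")
    require_artifacts(config, ins, "register")
    meshes <- lapply(seq_len(config$template_subjects),
                     function(i) read_mesh(mesh_path(i, "outer")))
    tmpl <- build_template(meshes, reference_index = 1L)
    tmpl_path <- file.path(config$out_dir, "template.ply")
    write_mesh(tmpl$mesh, tmpl_path)
    for (i in seq_len(n)) {
      pr <- propagate_template(tmpl, read_mesh(mesh_path(i, "outer")), align = TRUE)
      write_mesh(pr$resampled, res_path(i))
    }
    outs <- c(tmpl_path, vapply(seq_len(n), res_path, ""))
    stage_manifest(config, "register", ins, outs, t0,
                   counts = list(template_vertices = n_vertices(tmpl$mesh)))
    out$register <- outs
  }

  if ("thickness" %in% stages) {
    t0 <- as.numeric(Sys.time())
    ins <- c(vapply(seq_len(n), res_path, ""),
             vapply(seq_len(n), mesh_path, "", side = "inner"))
    require_artifacts(config, ins, "thickness")
    fields <- lapply(seq_len(n), function(i)
      compute_thickness(read_mesh(res_path(i)), read_mesh(mesh_path(i, "inner")),
                        subject_id = sprintf("S%04d", i)))
    qc <- qc_filter(fields, max_thickness_mm = config$qc_max_thickness_mm)
    keep <- vapply(fields, function(f) f$subject_id %in% qc$kept, logical(1))
    cm <- stack_cohort(fields[keep])
    thick_path <- file.path(config$out_dir, "thickness.csv")
    write_table(cbind(subject_id = cm$subject_ids,
                      as.data.frame(cm$values)), thick_path)
    qc_path <- file.path(config$out_dir, "qc_report.csv")
    write_table(qc$report, qc_path)
    stage_manifest(config, "thickness", ins, c(thick_path, qc_path), t0,
                   counts = list(kept = length(qc$kept), excluded = length(qc$excluded)))
    out$thickness <- cm
  }

  thickness_artifacts <- function() {
    p <- file.path(config$out_dir, "thickness.csv")
    require_artifacts(config, p, "downstream")
    tb <- read_table_strict(p)
    tmpl <- read_mesh(file.path(config$out_dir, "template.ply"))
    cohort_matrix(as.matrix(tb[, -1]), tb$subject_id, tmpl)
  }

  if ("spm" %in% stages) {
    t0 <- as.numeric(Sys.time())
    thick_path <- file.path(config$out_dir, "thickness.csv")
    cov_path <- file.path(config$out_dir, "covariates.csv")
    require_artifacts(config, c(thick_path, cov_path,
                                file.path(config$out_dir, "template.ply")), "spm")
    cm <- thickness_artifacts()
    covs <- read_table_strict(cov_path)
    covs <- covs[match(cm$subject_ids, covs$subject_id), ]
    vars <- intersect(c("age", "height", "vat_l"), names(covs))
    des <- design_matrix(covs, vars)
    spm <- run_spm(cm, des, config$spm)
    sum_path <- file.path(config$out_dir, "spm_summary.csv")
    write_table(spm$summary, sum_path)
    vtk_path <- file.path(config$out_dir, "spm_maps.vtk")
    write_mesh(cm$template, vtk_path,
               scalars = list(beta_std = spm$maps[[1]]$beta_std))
    stage_manifest(config, "spm", c(thick_path, cov_path), c(sum_path, vtk_path), t0)
    out$spm <- spm
  }

  if ("ssa" %in% stages) {
    t0 <- as.numeric(Sys.time())
    cm <- thickness_artifacts()
    model <- fit_spca(cm, k = min(config$spca_k, nrow(cm$values) - 1),
                      sparsity = config$spca_sparsity, seed = config$seed)
    sc_path <- file.path(config$out_dir, "pc_scores.csv")
    sc <- as.data.frame(model$scores)
    names(sc) <- paste0("PC", seq_len(ncol(sc)))
    write_table(cbind(subject_id = cm$subject_ids, sc), sc_path)
    ld_path <- file.path(config$out_dir, "pc_loadings.csv")
    write_table(as.data.frame(model$loadings), ld_path)
    stage_manifest(config, "ssa", file.path(config$out_dir, "thickness.csv"),
                   c(sc_path, ld_path), t0,
                   counts = list(k = model$k))
    out$ssa <- model
  }

  if ("survival" %in% stages) {
    t0 <- as.numeric(Sys.time())
    sc_path <- file.path(config$out_dir, "pc_scores.csv")
    cov_path <- file.path(config$out_dir, "covariates.csv")
    require_artifacts(config, c(sc_path, cov_path), "survival")
    cm <- thickness_artifacts()
    model <- out$ssa %||% fit_spca(cm, k = min(config$spca_k, nrow(cm$values) - 1),
                                   sparsity = config$spca_sparsity, seed = config$seed)
    scores <- read_table_strict(sc_path)
    sv_spec <- spec$survival %||% list(baseline_hazard = 0.08,
                                       log_hr = c(PC1 = 0.4), censor_time = 10)
    spec2 <- spec
    spec2$survival <- sv_spec
    surv <- generate_survival(spec2, scale(as.matrix(scores[, -1])) |>
                                as.data.frame() |> setNames(names(scores)[-1]))
    surv <- surv[match(cm$subject_ids, surv$subject_id), ]
    covs <- read_table_strict(cov_path)
    covs$volume <- rowMeans(cm$values)[match(covs$subject_id, cm$subject_ids)]
    covs <- covs[!is.na(covs$volume), ]
    study <- run_survival_study(surv, covs, model, cm,
                                adjustment = config$survival_adjustment,
                                n_pcs = min(config$spca_k, model$k))
    hr_path <- file.path(config$out_dir, "survival_hr.csv")
    write_table(study$hr_table, hr_path)
    cmp_path <- file.path(config$out_dir, "survival_comparison.json")
    jsonlite::write_json(list(comparison = study$comparison,
                              winner = attr(study$comparison, "winner")),
                         cmp_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stage_manifest(config, "survival", c(sc_path, cov_path), c(hr_path, cmp_path), t0)
    out$survival <- study
  }

  invisible(out)
}
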