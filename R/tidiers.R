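#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an SPM result into its covariate x sign summary
#' @param x An `spm_result`.
#' @param ... Unused.
#' @return The summary tibble (see [summarize_spm()]).
#' @method tidy spm_result
#' @export
tidy.spm_result <- function(x, ...) x$summary

#' @method glance spm_result
#' @export
glance.spm_result <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects,
                 n_vertices = n_vertices(x$template),
                 n_covariates = length(x$maps),
                 n_permutations = x$config$n_permutations,
                 fdr_q = x$config$fdr_q,
                 tfce_E = x$config$tfce_E, tfce_H = x$config$tfce_H)
}

#' Tidy per-term longitudinal mixed-model maps
#' @param x An `lmm_map_result`.
#' @param ... Unused.
#' @return Tibble: term, vertex, estimate, se, p, significant.
#' @method tidy lmm_map_result
#' @export
tidy.lmm_map_result <- function(x, ...) {
  terms <- rownames(x$estimates)
  purrr::map_dfr(terms, function(tm) tibble::tibble(
    term = tm, vertex = seq_len(ncol(x$estimates)),
    estimate = x$estimates[tm, ], se = x$se[tm, ], p = x$p[tm, ],
    significant = if (tm %in% names(x$masks)) x$masks[[tm]] else NA))
}

#' @method glance lmm_map_result
#' @export
glance.lmm_map_result <- function(x, ...) {
  tibble::tibble(n_vertices = ncol(x$estimates),
                 median_sigma_b2 = median(x$sigma_b2),
                 median_sigma2 = median(x$sigma2),
                 fdr_q = x$fdr_q)
}

#' Tidy sparse-PCA loadings/variance
#' @param x An `spca_model`.
#' @param ... Unused.
#' @return Tibble: component, variance, adjusted/cumulative explained
#'   fractions, sparsity fraction.
#' @method tidy spca_model
#' @export
tidy.spca_model <- function(x, ...) {
  tibble::tibble(component = seq_len(x$k),
                 variance = x$component_variance,
                 adjusted_explained = x$adjusted_explained,
                 cumulative_explained = x$cumulative_explained,
                 sparsity_fraction = x$sparsity_fraction)
}

#' @method glance spca_model
#' @export
glance.spca_model <- function(x, ...) {
  tibble::tibble(k = x$k, sparsity = x$sparsity,
                 total_variance = x$total_variance,
                 cumulative_explained = tail(x$cumulative_explained, 1))
}

#' Tidy Cox hazard ratios
#' @param x A `cox_fit`.
#' @param ... Unused.
#' @return The coefficient tibble (term, estimate, se, hr, ci, p).
#' @method tidy cox_fit
#' @export
tidy.cox_fit <- function(x, ...) x$coefficients

#' @method glance cox_fit
#' @export
glance.cox_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events, loglik = x$loglik,
                 aic = x$aic, c_index = x$c_index)
}

#' @method tidy survival_study
#' @export
tidy.survival_study <- function(x, ...) x$hr_table

#' @method glance survival_study
#' @export
glance.survival_study <- function(x, ...) {
  w <- attr(x$comparison, "winner")
  tibble::tibble(aic_volume = x$fit_volume$aic,
                 aic_thickness = x$fit_thickness$aic,
                 c_index_volume = x$fit_volume$c_index,
                 c_index_thickness = x$fit_thickness$c_index,
                 winner_aic = w$aic, winner_c_index = w$c_index)
}
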