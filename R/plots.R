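# All maps are drawn as longitude/latitude projections of the template
# vertex directions; for the near-ellipsoidal surfaces this pipeline
# analyses that flattening is faithful enough for QC and reporting.

mesh_lonlat <- function(mesh) {
  u <- mesh$vertices - matrix(colMeans(mesh$vertices), nrow(mesh$vertices), 3,
                              byrow = TRUE)
  u <- u / sqrt(rowSums(u^2))
  tibble::tibble(lon = atan2(u[, 2], u[, 1]), lat = asin(pmin(pmax(u[, 3], -1), 1)))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a per-vertex field as a flattened surface map
#' @param object A [vertex_field()] (e.g. a thickness field).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot vertex_field
#' @export
autoplot.vertex_field <- function(object, ...) {
  df <- mesh_lonlat(object$mesh)
  df$value <- object$values
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat, colour = .data$value)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_viridis_c(name = object$unit) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "longitude (rad)", y = "latitude (rad)") +
    ggplot2::theme_minimal()
}

#' Statistical parametric map of one covariate
#'
#' Standardised coefficients over the flattened template, with vertices
#' significant after TFCE + permutation + FDR outlined in black, split by
#' effect sign as in the study's map figures.
#'
#' @param object An `spm_result`.
#' @param covariate Which covariate map to draw (default: first).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot spm_result
#' @export
autoplot.spm_result <- function(object, covariate = names(object$maps)[1], ...) {
  m <- object$maps[[covariate]]
  df <- mesh_lonlat(object$template)
  df$beta <- m$beta_std
  df$sig <- ifelse(m$sig_pos, "positive", ifelse(m$sig_neg, "negative", "ns"))
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$beta), size = 0.8) +
    ggplot2::geom_point(data = df[df$sig != "ns", ],
                        shape = 21, size = 1.4, stroke = 0.3, fill = NA,
                        colour = "black") +
    ggplot2::scale_colour_gradient2(low = "blue", mid = "grey90", high = "red",
                                    name = expression(hat(beta))) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = covariate, x = "longitude (rad)", y = "latitude (rad)") +
    ggplot2::theme_minimal()
}

#' Loading map of one sparse principal component
#' @param object An `spca_model` fitted to a [cohort_matrix()] carrying its
#'   template.
#' @param component Component index.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot spca_model
#' @export
autoplot.spca_model <- function(object, component = 1L, ...) {
  if (is.null(object$template)) abort("model carries no template mesh to plot on")
  df <- mesh_lonlat(object$template)
  df$loading <- object$loadings[, component]
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat, colour = .data$loading)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_gradient2(low = "blue", mid = "grey90", high = "red") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("PC%d (%.1f%% adj. variance)", component,
                                  100 * object$adjusted_explained[component]),
                  x = "longitude (rad)", y = "latitude (rad)") +
    ggplot2::theme_minimal()
}

#' Forest plot of hazard ratios
#' @param object A `cox_fit` or `survival_study`.
#' @param ... Unused.
#' @return A ggplot with HR point estimates and 95% CIs on a log scale.
#' @method autoplot cox_fit
#' @export
autoplot.cox_fit <- function(object, ...) {
  df <- object$coefficients
  ggplot2::ggplot(df, ggplot2::aes(.data$hr, .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_lo, xmax = .data$ci_hi)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "hazard ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.cox_fit
#' @method autoplot survival_study
#' @export
autoplot.survival_study <- function(object, ...) {
  df <- object$hr_table
  ggplot2::ggplot(df, ggplot2::aes(.data$hr, .data$term, colour = .data$q < 0.05)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_lo, xmax = .data$ci_hi)) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "red", `FALSE` = "grey30"),
                                 name = "FDR < 0.05") +
    ggplot2::facet_wrap(~model, scales = "free_y") +
    ggplot2::labs(x = "hazard ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
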