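#' Design matrix for vertex-wise regression
#'
#' Builds an intercept + covariates design from a data frame. Columns taking
#' only the values {0, 1} are treated as binary (left unstandardised);
#' everything else is flagged continuous and z-scored by [standardize()].
#'
#' @param data Data frame of covariates (one row per subject).
#' @param covariates Character vector of column names to include.
#' @param binary Optional explicit character vector of binary columns
#'   (defaults to auto-detection of 0/1 columns).
#' @return A `design_matrix`: `X` (n x p with intercept), `continuous`
#'   (logical per column), `names`.
#' @export
design_matrix <- function(data, covariates, binary = NULL) {
  miss <- setdiff(covariates, names(data))
  if (length(miss)) abort(sprintf("covariates not found: %s", paste(miss, collapse = ",")))
  X <- cbind(`(intercept)` = 1, as.matrix(as.data.frame(data)[covariates]))
  storage.mode(X) <- "double"
  if (is.null(binary))
    binary <- covariates[vapply(covariates, function(c3)
      all(data[[c3]] %in% c(0, 1)), logical(1))]
  continuous <- c(FALSE, !covariates %in% binary)
  names(continuous) <- colnames(X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(sprintf("design matrix is rank deficient; collinear columns: %s",
                  paste(dropped, collapse = ",")))
  }
  structure(list(X = X, continuous = continuous, names = colnames(X)),
            class = "design_matrix")
}

#' Standardise design and response
#'
#' Z-scores (mean 0, SD 1, `n - 1` denominator) every continuous design
#' column and every response column; binary columns and the intercept are
#' untouched. The centring/scaling parameters are recorded so estimates can
#' be mapped back to original units.
#'
#' @param design A [design_matrix()].
#' @param response A [cohort_matrix()] or plain matrix.
#' @return List: `design` (standardised [design_matrix()]), `response`
#'   (standardised matrix), `x_center`, `x_scale`, `y_center`, `y_scale`.
#' @export
standardize <- function(design, response) {
  X <- design$X
  x_center <- setNames(numeric(ncol(X)), colnames(X))
  x_scale <- setNames(rep(1, ncol(X)), colnames(X))
  for (j in which(design$continuous)) {
    s <- sd(X[, j])
    if (!is.finite(s) || s == 0)
      abort(sprintf("zero-variance continuous column '%s'", colnames(X)[j]))
    x_center[j] <- mean(X[, j]); x_scale[j] <- s
    X[, j] <- (X[, j] - x_center[j]) / s
  }
  Y <- if (inherits(response, "cohort_matrix")) response$values else as.matrix(response)
  y_center <- colMeans(Y)
  y_scale <- apply(Y, 2, sd)
  y_scale[y_scale == 0] <- 1
  Ys <- sweep(sweep(Y, 2, y_center), 2, y_scale, "/")
  design$X <- X
  list(design = design, response = Ys,
       x_center = x_center, x_scale = x_scale,
       y_center = y_center, y_scale = y_scale)
}

#' Vertex-wise ordinary least squares
#'
#' Fits `y_v ~ X` at every vertex simultaneously through one shared
#' pseudo-inverse; returns coefficient, t (with `n - p` df) and residual
#' maps. A zero-residual (perfect-fit) vertex yields a large finite t rather
#' than infinity.
#'
#' @param response n x V response matrix (typically standardised thickness).
#' @param design A [design_matrix()] (typically standardised).
#' @return List: `beta` (p x V), `t` (p x V), `se`, `residuals` (n x V),
#'   `sigma2`, `df`.
#' @export
vertexwise_ols <- function(response, design) {
  X <- design$X
  n <- nrow(X); p <- ncol(X)
  if (n <= p) abort("need more subjects than design columns")
  XtXi <- solve(crossprod(X))
  P <- XtXi %*% t(X)
  B <- P %*% response
  res <- response - X %*% B
  df <- n - p
  sigma2 <- colSums(res^2) / df
  cjj <- diag(XtXi)
  se <- sqrt(outer(cjj, pmax(sigma2, 1e-300)))
  tmap <- B / se
  tmap <- pmin(pmax(tmap, -1e15), 1e15)
  tmap[B == 0 & se == 0] <- 0
  dimnames(B) <- dimnames(tmap) <- list(colnames(X), NULL)
  list(beta = B, t = tmap, se = se, residuals = res, sigma2 = sigma2, df = df)
}

#' Configuration for the statistical-parametric-map stage
#'
#' TFCE defaults E = 0.5, H = 2 (the canonical extent/height exponents for
#' surface data) with 100 integration steps.
#'
#' @param tfce_E,tfce_H TFCE extent and height exponents (> 0).
#' @param n_steps Number of threshold steps (>= 10).
#' @param n_permutations Permutations for inference (>= 100 recommended).
#' @param fdr_q FDR level in (0, 1).
#' @param seed Permutation RNG seed.
#' @param extent_mode `"vertex_count"` or `"area_weighted"` cluster extent.
#' @return An `spm_config` list.
#' @export
spm_config <- function(tfce_E = 0.5, tfce_H = 2, n_steps = 100L,
                       n_permutations = 500L, fdr_q = 0.05, seed = 1L,
                       extent_mode = c("vertex_count", "area_weighted")) {
  stopifnot(tfce_E > 0, tfce_H > 0, n_steps >= 10,
            fdr_q > 0, fdr_q < 1)
  structure(list(tfce_E = tfce_E, tfce_H = tfce_H, n_steps = as.integer(n_steps),
                 n_permutations = as.integer(n_permutations), fdr_q = fdr_q,
                 seed = as.integer(seed), extent_mode = match.arg(extent_mode)),
            class = "spm_config")
}

#' Threshold-free cluster enhancement on a mesh statistic map
#'
#' `TFCE(v) = sum_{h = dh, 2dh, ..., h_max} e_v(h)^E * h^H * dh` with
#' `e_v(h)` the extent (vertex count, or summed vertex area) of the
#' supra-threshold connected component containing `v`, and
#' `dh = h_max / n_steps`. Output is 0 wherever the statistic is <= 0;
#' negative effects are enhanced by passing `-stat`.
#'
#' @param stat Finite per-vertex statistic vector.
#' @param edges 2-column edge matrix ([mesh_edges()]).
#' @param areas Per-vertex areas (used when `extent_mode = "area_weighted"`).
#' @param config An [spm_config()].
#' @return Numeric TFCE map.
#' @export
tfce_enhance <- function(stat, edges, areas = NULL, config = spm_config()) {
  if (any(!is.finite(stat))) abort("statistic map contains non-finite values")
  nv <- length(stat)
  w <- if (config$extent_mode == "area_weighted") {
    if (is.null(areas)) abort("area_weighted extent needs vertex areas")
    areas
  } else rep(1, nv)
  cpp_tfce(as.numeric(stat), edges, as.numeric(w),
           config$tfce_E, config$tfce_H, config$n_steps)
}

#' Permutation inference for one covariate (Freedman-Lane)
#'
#' The reduced model without the covariate of interest is fitted, its
#' residuals are permuted across subjects with a seeded generator, the full
#' model is refitted on each permuted response, and the covariate's t map is
#' TFCE-enhanced for both signs. Per-vertex p values are
#' `(1 + #{perm TFCE >= observed TFCE}) / (n_perm + 1)`, computed separately
#' for positive and negative effects, so p always lies in
#' `[1/(n_perm+1), 1]`.
#'
#' @param response Standardised n x V response matrix.
#' @param design Standardised [design_matrix()].
#' @param variable Name of the design column to test.
#' @param edges,areas Mesh combinatorics for TFCE.
#' @param config An [spm_config()].
#' @return List: `p_pos`, `p_neg`, `tfce_pos`, `tfce_neg`, `t_obs`,
#'   `beta_obs`.
#' @export
permutation_inference <- function(response, design, variable, edges,
                                  areas = NULL, config = spm_config()) {
  X <- design$X
  j <- match(variable, colnames(X))
  if (is.na(j)) abort(sprintf("variable '%s' not in design", variable))
  n <- nrow(X)
  fit <- vertexwise_ols(response, design)
  t_obs <- fit$t[j, ]
  tfce_pos <- tfce_enhance(t_obs, edges, areas, config)
  tfce_neg <- tfce_enhance(-t_obs, edges, areas, config)

  Xr <- X[, -j, drop = FALSE]
  Pr <- solve(crossprod(Xr)) %*% t(Xr)
  fitted_red <- Xr %*% (Pr %*% response)
  res_red <- response - fitted_red

  XtXi <- solve(crossprod(X))
  P <- XtXi %*% t(X)
  cjj <- XtXi[j, j]
  df <- n - ncol(X)

  cnt_pos <- numeric(length(t_obs))
  cnt_neg <- numeric(length(t_obs))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  for (b in seq_len(config$n_permutations)) {
    perm <- sample.int(n)
    Yp <- fitted_red + res_red[perm, , drop = FALSE]
    Bp <- P %*% Yp
    resp <- Yp - X %*% Bp
    s2 <- pmax(colSums(resp^2) / df, 1e-300)
    tp <- Bp[j, ] / sqrt(cjj * s2)
    cnt_pos <- cnt_pos + (tfce_enhance(tp, edges, areas, config) >= tfce_pos)
    cnt_neg <- cnt_neg + (tfce_enhance(-tp, edges, areas, config) >= tfce_neg)
  }
  np <- config$n_permutations
  list(p_pos = (1 + cnt_pos) / (np + 1),
       p_neg = (1 + cnt_neg) / (np + 1),
       tfce_pos = tfce_pos, tfce_neg = tfce_neg,
       t_obs = t_obs, beta_obs = fit$beta[j, ])
}

#' Benjamini-Hochberg FDR significance mask
#'
#' Step-up BH over all vertices of a p map: sort ascending, find the largest
#' k with `p_(k) <= k q / m`, reject the k smallest.
#'
#' @param p Vector of p values in (0, 1].
#' @param q FDR level.
#' @return Logical rejection mask (possibly empty).
#' @export
bh_fdr <- function(p, q = 0.05) {
  p.adjust(p, method = "BH") <= q
}

#' Run the full mass-univariate SPM stage
#'
#' Standardises design and response, then for each requested covariate runs
#' OLS + TFCE + Freedman-Lane permutations and BH-FDR within each sign map,
#' mirroring the sign-split significance-area reporting of vertex-wise
#' morphometry studies.
#'
#' @param cohort A [cohort_matrix()].
#' @param design A [design_matrix()] (unstandardised; this function
#'   standardises).
#' @param config An [spm_config()].
#' @param variables Design columns to test (default: all but the intercept).
#' @return An `spm_result` with per-covariate maps and a summary tibble
#'   (see [summarize_spm()]); `tidy()` returns the summary.
#' @export
run_spm <- function(cohort, design, config = spm_config(), variables = NULL) {
  std <- standardize(design, cohort)
  tmpl <- cohort$template
  edges <- mesh_edges(tmpl)
  areas <- vertex_areas(tmpl)
  if (is.null(variables)) variables <- setdiff(colnames(std$design$X), "(intercept)")
  maps <- list()
  for (v in variables) {
    pi <- permutation_inference(std$response, std$design, v, edges, areas, config)
    sig_pos <- bh_fdr(pi$p_pos, config$fdr_q)
    sig_neg <- bh_fdr(pi$p_neg, config$fdr_q)
    # original-units coefficient: mm of thickness per unit of the covariate
    beta_mm <- pi$beta_obs * std$y_scale / std$x_scale[v]
    maps[[v]] <- list(beta_std = pi$beta_obs, beta_mm = beta_mm,
                      t = pi$t_obs, tfce_pos = pi$tfce_pos,
                      tfce_neg = pi$tfce_neg, p_pos = pi$p_pos,
                      p_neg = pi$p_neg, sig_pos = sig_pos, sig_neg = sig_neg)
  }
  res <- structure(list(maps = maps, template = tmpl, config = config,
                        areas = areas, n_subjects = nrow(std$response)),
                   class = "spm_result")
  res$summary <- summarize_spm(res)
  res
}

#' @export
print.spm_result <- function(x, ...) {
  cat(sprintf("<spm_result> %d covariates x %d vertices, %d permutations\n",
              length(x$maps), n_vertices(x$template), x$config$n_permutations))
  print(x$summary)
  invisible(x)
}

#' Summary table of an SPM result
#'
#' Per covariate and per effect sign: the median and IQR of the regression
#' coefficient over the significant vertices of that sign (standardised and
#' in mm per covariate unit), and the significance area as a percentage of
#' vertices (or of total surface area under area-weighted extents). Empty
#' masks report NA medians and 0% area.
#'
#' @param result An `spm_result`.
#' @return Tibble with one row per covariate x sign.
#' @export
summarize_spm <- function(result) {
  cfg <- result$config
  total_w <- if (cfg$extent_mode == "area_weighted") sum(result$areas)
             else length(result$areas)
  rows <- list()
  for (v in names(result$maps)) {
    m <- result$maps[[v]]
    for (sgn in c("positive", "negative")) {
      mask <- if (sgn == "positive") m$sig_pos else m$sig_neg
      w <- if (cfg$extent_mode == "area_weighted") sum(result$areas[mask])
           else sum(mask)
      rows[[length(rows) + 1]] <- tibble::tibble(
        covariate = v, sign = sgn,
        n_significant = sum(mask),
        significance_area_pct = 100 * w / total_w,
        median_beta_std = if (any(mask)) median(m$beta_std[mask]) else NA_real_,
        iqr_beta_std = if (any(mask)) stats::IQR(m$beta_std[mask]) else NA_real_,
        median_beta_mm = if (any(mask)) median(m$beta_mm[mask]) else NA_real_,
        iqr_beta_mm = if (any(mask)) stats::IQR(m$beta_mm[mask]) else NA_real_)
    }
  }
  dplyr::bind_rows(rows)
}
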