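#' Sparse principal component analysis of a thickness matrix
#'
#' Robust statistical shape analysis of the cohort thickness matrix: the
#' matrix is centred by the per-vertex *median*, then decomposed by
#' alternating-regression sparse PCA — rank-1 power iterations with an L1
#' soft-threshold on the loading vector, deflating between components. With
#' `sparsity = 0` the decomposition is exactly classical PCA (leading
#' singular pairs), which anchors the implementation; positive `sparsity`
#' localises each loading on the surface. Scores may optionally be
#' winsorised at 4 MADs for robustness to outlying shapes.
#'
#' Explained variance for sparse (correlated) components uses the
#' QR-adjusted variance of the score matrix, avoiding double counting.
#'
#' @param cohort A [cohort_matrix()] (or plain subjects x vertices matrix).
#' @param k Number of components (`k <= min(n - 1, V)`).
#' @param sparsity Non-negative L1 soft-threshold applied to the loading
#'   update (0 = classical PCA).
#' @param seed Seed for the (deterministic svd-based) initialisation; kept
#'   for interface stability.
#' @param winsorize_scores Clamp scores at 4 MADs from their median.
#' @param max_iter,tol Alternation controls.
#' @return An `spca_model`: `loadings` (V x k, unit columns, largest entry
#'   positive), `scores` (n x k), `center` (per-vertex medians),
#'   `component_variance`, `adjusted_explained`, `cumulative_explained`,
#'   `sparsity_fraction`, `total_variance`.
#' @export
fit_spca <- function(cohort, k = 4L, sparsity = 0, seed = 1L,
                     winsorize_scores = FALSE, max_iter = 200L, tol = 1e-10) {
  Y <- if (inherits(cohort, "cohort_matrix")) cohort$values else as.matrix(cohort)
  template <- if (inherits(cohort, "cohort_matrix")) cohort$template else NULL
  n <- nrow(Y); V <- ncol(Y)
  if (k > min(n - 1, V)) abort(sprintf("k = %d exceeds min(n - 1, V) = %d", k, min(n - 1, V)))
  if (any(!is.finite(Y))) abort("thickness matrix contains non-finite values")
  ctr <- apply(Y, 2, median)
  Xc <- sweep(Y, 2, ctr)
  R <- Xc
  W <- matrix(0, V, k)
  for (j in seq_len(k)) {
    sv <- svd(R, nu = 1, nv = 1)
    v <- sv$v[, 1]
    for (it in seq_len(max_iter)) {
      u <- as.numeric(R %*% v)
      nu <- sqrt(sum(u^2))
      if (nu < 1e-300) break
      u <- u / nu
      w <- as.numeric(crossprod(R, u))
      w <- sign(w) * pmax(abs(w) - sparsity, 0)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-300) {
        # threshold killed the loading entirely; keep the largest entry
        w <- numeric(V)
        w[which.max(abs(as.numeric(crossprod(R, u))))] <- 1
        nw <- 1
      }
      w <- w / nw
      if (sum((w - v)^2) < tol) { v <- w; break }
      v <- w
    }
    # deterministic sign: largest-magnitude entry positive
    if (v[which.max(abs(v))] < 0) v <- -v
    W[, j] <- v
    u <- as.numeric(R %*% v)
    R <- R - outer(u, v)
  }
  S <- Xc %*% W
  if (winsorize_scores) {
    for (j in seq_len(k)) {
      md <- median(S[, j]); bound <- 4 * mad(S[, j])
      S[, j] <- pmin(pmax(S[, j], md - bound), md + bound)
    }
  }
  qrS <- qr(S)
  Rdiag <- abs(diag(qr.R(qrS)))[seq_len(k)]
  adj <- Rdiag^2 / (n - 1)
  total <- sum(Xc^2) / (n - 1)
  structure(list(
    loadings = W, scores = S, center = ctr, k = k, sparsity = sparsity,
    component_variance = colSums(S^2) / (n - 1),
    adjusted_explained = adj / total,
    cumulative_explained = cumsum(adj) / total,
    sparsity_fraction = colMeans(W == 0),
    total_variance = total,
    template = template, winsorized = winsorize_scores),
    class = "spca_model")
}

#' @export
print.spca_model <- function(x, ...) {
  cat(sprintf("<spca_model> %d components over %d vertices; cumulative adjusted variance %.1f%%\n",
              x$k, nrow(x$loadings), 100 * tail(x$cumulative_explained, 1)))
  invisible(x)
}

#' Project new thickness data onto a fitted shape model
#'
#' `scores = (Y - center) %*% loadings`; applying it to the training matrix
#' reproduces the stored scores (before any winsorisation).
#'
#' @param model An `spca_model`.
#' @param cohort A [cohort_matrix()] or matrix with matching vertex count.
#' @return n x k score matrix.
#' @export
spca_transform <- function(model, cohort) {
  Y <- if (inherits(cohort, "cohort_matrix")) cohort$values else as.matrix(cohort)
  if (ncol(Y) != nrow(model$loadings))
    abort("vertex count does not match the fitted model")
  sweep(Y, 2, model$center) %*% model$loadings
}

#' @export
predict.spca_model <- function(object, newdata, ...) spca_transform(object, newdata)

#' Reconstruct the thickness field at a given score deviation
#'
#' `field = mean + t * SD(score_j) * loading_j`: the thickness pattern a
#' subject `t` standard deviations along component `j` would show, used to
#' render what each shape component means anatomically (e.g. -3 to +3 SD).
#'
#' @param model An `spca_model`.
#' @param mean_field Per-vertex mean (or median) thickness; defaults to the
#'   model centre.
#' @param component Component index.
#' @param t Deviation in score SDs (|t| <= 5).
#' @return Numeric per-vertex field (a [vertex_field()] if the model carries
#'   its template).
#' @export
shape_at_sd <- function(model, mean_field = NULL, component = 1L, t = 0) {
  if (abs(t) > 5) abort("|t| > 5 SD is outside the sane rendering range")
  mu <- mean_field %||% model$center
  if (inherits(mu, "vertex_field")) mu <- mu$values
  sdj <- sd(model$scores[, component])
  out <- mu + t * sdj * model$loadings[, component]
  if (!is.null(model$template)) vertex_field(out, model$template, unit = "mm") else out
}
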