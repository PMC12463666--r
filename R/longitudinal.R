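# Random-intercept LMM machinery.
#
# Model per vertex: y = X beta + Z b + e, b ~ N(0, sigma_b^2), e ~ N(0, sigma^2),
# Z the subject indicator. With rho = sigma_b^2 / sigma^2 and
# V0 = I + rho Z Z', Woodbury gives V0^{-1} = I - Z diag(d) Z',
# d_i = rho / (1 + rho * n_i), so every REML quantity reduces to
# subject-aggregated sufficient statistics and profiling over the single
# ratio rho is cheap. Fixed effects are GLS at rho-hat; p values use the
# normal (Wald) reference, a negligible approximation at the cohort sizes
# this stage targets.

lmm_suffstats <- function(X, subject) {
  subject <- as.factor(subject)
  m <- nlevels(subject)
  n_i <- as.numeric(table(subject))
  ZtX <- rowsum(X, subject)          # m x p
  list(XtX = crossprod(X), ZtX = ZtX, n_i = n_i, subject = subject,
       n = nrow(X), p = ncol(X), m = m)
}

# -2 REML log-likelihood (up to an additive constant) at ratio rho
lmm_reml_crit <- function(rho, ss, Xty, Zty, yty) {
  d <- rho / (1 + rho * ss$n_i)
  M <- ss$XtX - crossprod(ss$ZtX * d, ss$ZtX)
  XtViy <- Xty - crossprod(ss$ZtX * d, Zty)
  yViy <- yty - sum(d * Zty^2)
  beta <- solve(M, XtViy)
  rss <- yViy - sum(XtViy * beta)
  sum(log1p(rho * ss$n_i)) + determinant(M, logarithm = TRUE)$modulus[1] +
    (ss$n - ss$p) * log(max(rss, 1e-300))
}

#' Fit a random-intercept linear mixed model at one vertex
#'
#' REML estimation by 1-D profiling of the variance ratio
#' `rho = sigma_b^2 / sigma^2` (coarse bracketing grid + golden-section via
#' [stats::optimize()]), then GLS for the fixed effects at the estimate.
#' Wald p values use the normal reference.
#'
#' @param y Response vector (one vertex).
#' @param X Fixed-effects design matrix (with intercept).
#' @param subject Subject identifier per observation (random intercept).
#' @return List: `coefficients` tibble (term, estimate, se, z, p),
#'   `sigma_b2`, `sigma2`, `rho`, `reml`.
#' @export
fit_vertex_lmm <- function(y, X, subject) {
  X <- as.matrix(X)
  ss <- lmm_suffstats(X, subject)
  if (sum(ss$n_i >= 2) < 2)
    abort("random intercept unidentifiable: fewer than 2 subjects with repeated visits")
  if (qr(X)$rank < ncol(X)) abort("fixed-effects design is rank deficient")
  Xty <- crossprod(X, y)
  Zty <- rowsum(y, ss$subject)[, 1]
  yty <- sum(y^2)
  crit <- function(r) lmm_reml_crit(r, ss, Xty, Zty, yty)
  grid <- c(0, 10^seq(-4, 4, length.out = 33))
  cv <- vapply(grid, crit, numeric(1))
  k <- which.min(cv)
  lo <- grid[max(1, k - 1)]; hi <- grid[min(length(grid), k + 1)]
  rho <- if (k == 1 && cv[1] <= cv[2]) {
    opt <- optimize(crit, c(0, grid[2]))
    if (crit(0) <= opt$objective) 0 else opt$minimum
  } else optimize(crit, c(lo, hi))$minimum
  lmm_gls(rho, ss, Xty, Zty, yty, colnames(X))
}

lmm_gls <- function(rho, ss, Xty, Zty, yty, terms) {
  d <- rho / (1 + rho * ss$n_i)
  M <- ss$XtX - crossprod(ss$ZtX * d, ss$ZtX)
  XtViy <- Xty - crossprod(ss$ZtX * d, Zty)
  yViy <- yty - sum(d * Zty^2)
  Minv <- solve(M)
  beta <- as.numeric(Minv %*% XtViy)
  rss <- max(yViy - sum(XtViy * beta), 0)
  sigma2 <- rss / (ss$n - ss$p)
  se <- unname(sqrt(pmax(diag(Minv) * sigma2, 0)))
  z <- ifelse(se > 0, beta / se, 0)
  list(coefficients = tibble::tibble(
         term = terms %||% paste0("x", seq_along(beta)),
         estimate = beta, se = se, z = z, p = 2 * pnorm(-abs(z))),
       sigma_b2 = rho * sigma2, sigma2 = sigma2, rho = rho,
       reml = lmm_reml_crit(rho, ss, Xty, Zty, yty))
}

#' Vertex-wise longitudinal mixed-model maps
#'
#' Fits the random-intercept LMM at every template vertex for a two-visit
#' cohort. The fixed effects are visit (0 = baseline, 1 = follow-up), the
#' disease indicator, their interaction, and any additional covariates
#' (continuous ones standardised); the response stays in mm so visit
#' effects read as mm change. The profile REML criterion is evaluated on a
#' shared fine grid of variance ratios for all vertices at once, refined by
#' parabolic interpolation in log-rho, then GLS is solved per vertex.
#' BH-FDR is applied per fixed-effect map.
#'
#' @param table Longitudinal tibble: `subject_id`, `visit` (0/1), disease
#'   indicator and covariate columns; 1 or 2 rows per subject.
#' @param thickness_v1,thickness_v2 [cohort_matrix()] per visit (rows
#'   matched to subjects by id).
#' @param disease Name of the binary disease/condition column.
#' @param covariates Extra fixed-effect columns (may be empty).
#' @param fdr_q FDR level for the per-term masks.
#' @return An `lmm_map_result`: per-term estimate/se/p matrices, variance
#'   components, FDR masks, and a visit-change summary tibble (median mm
#'   change over significant vertices, split by sign).
#' @export
run_longitudinal_map <- function(table, thickness_v1, thickness_v2,
                                 disease = "disease", covariates = character(),
                                 fdr_q = 0.05) {
  stopifnot(all(table$visit %in% c(0, 1)))
  ids1 <- thickness_v1$subject_ids
  ids2 <- thickness_v2$subject_ids
  if (ncol(thickness_v1$values) != ncol(thickness_v2$values))
    abort("visit matrices are on different templates")
  rows <- lapply(seq_len(nrow(table)), function(i) {
    id <- table$subject_id[i]
    if (table$visit[i] == 0) thickness_v1$values[match(id, ids1), ]
    else thickness_v2$values[match(id, ids2), ]
  })
  Y <- do.call(rbind, rows)
  if (anyNA(Y)) abort("longitudinal table references subjects missing from a visit matrix")

  Xdf <- data.frame(visit = table$visit, disease = table[[disease]])
  for (cv in covariates) {
    x <- table[[cv]]
    if (!all(x %in% c(0, 1))) x <- (x - mean(x)) / sd(x)
    Xdf[[cv]] <- x
  }
  X <- cbind(`(intercept)` = 1, as.matrix(Xdf),
             `visit:disease` = table$visit * table[[disease]])
  ss <- lmm_suffstats(X, table$subject_id)
  if (sum(ss$n_i >= 2) < 2)
    abort("random intercept unidentifiable: fewer than 2 subjects with repeated visits")

  XtY <- crossprod(X, Y)                       # p x V
  S <- rowsum(Y, ss$subject)                   # m x V
  yty <- colSums(Y^2)
  nv <- ncol(Y); p <- ncol(X); n <- nrow(Y)

  grid <- c(0, 10^seq(-4, 4, length.out = 161))
  crit_all <- function(rho) {
    d <- rho / (1 + rho * ss$n_i)
    M <- ss$XtX - crossprod(ss$ZtX * d, ss$ZtX)
    XtViY <- XtY - crossprod(ss$ZtX * d, S)
    yViy <- yty - colSums(S^2 * d)
    sol <- solve(M, XtViY)
    rss <- pmax(yViy - colSums(XtViY * sol), 1e-300)
    sum(log1p(rho * ss$n_i)) + determinant(M, logarithm = TRUE)$modulus[1] +
      (n - p) * log(rss)
  }
  C <- vapply(grid, crit_all, numeric(nv))     # V x n_grid
  k <- max.col(-C, ties.method = "first")
  rho_hat <- grid[k]
  # parabolic refinement in log10(rho) for interior minima
  interior <- which(k > 2 & k < length(grid))
  if (length(interior)) {
    lg <- log10(grid[-1])
    kk <- k[interior] - 1                       # index into lg
    x0 <- lg[kk - 1]; x1 <- lg[kk]; x2 <- lg[kk + 1]
    y0 <- C[cbind(interior, k[interior] - 1)]
    y1 <- C[cbind(interior, k[interior])]
    y2 <- C[cbind(interior, k[interior] + 1)]
    denom <- (y0 - 2 * y1 + y2)
    shift <- ifelse(abs(denom) > 1e-12,
                    0.5 * (y0 - y2) / denom * (x2 - x1), 0)
    rho_hat[interior] <- 10^(x1 + pmin(pmax(shift, -(x1 - x0)), x2 - x1))
  }

  est <- se <- matrix(0, p, nv, dimnames = list(colnames(X), NULL))
  sigma2 <- sigma_b2 <- numeric(nv)
  for (v in seq_len(nv)) {
    g <- lmm_gls(rho_hat[v], ss, XtY[, v], S[, v], yty[v], colnames(X))
    est[, v] <- g$coefficients$estimate
    se[, v] <- g$coefficients$se
    sigma2[v] <- g$sigma2
    sigma_b2[v] <- g$sigma_b2
  }
  z <- ifelse(se > 0, est / se, 0)
  pmat <- 2 * pnorm(-abs(z))
  terms <- setdiff(colnames(X), "(intercept)")
  masks <- lapply(setNames(terms, terms), function(tm) bh_fdr(pmat[tm, ], fdr_q))

  vis <- "visit"
  msk <- masks[[vis]]
  pos <- msk & est[vis, ] > 0
  neg <- msk & est[vis, ] < 0
  summary <- tibble::tibble(
    term = vis, sign = c("positive", "negative"),
    n_significant = c(sum(pos), sum(neg)),
    median_change_mm = c(if (any(pos)) median(est[vis, pos]) else NA_real_,
                         if (any(neg)) median(est[vis, neg]) else NA_real_))
  structure(list(estimates = est, se = se, p = pmat, masks = masks,
                 sigma2 = sigma2, sigma_b2 = sigma_b2, rho = rho_hat,
                 template = thickness_v1$template, fdr_q = fdr_q,
                 summary = summary),
            class = "lmm_map_result")
}

#' @export
print.lmm_map_result <- function(x, ...) {
  cat(sprintf("<lmm_map_result> %d terms x %d vertices\n",
              nrow(x$estimates), ncol(x$estimates)))
  print(x$summary)
  invisible(x)
}
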