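#' Fit a Cox proportional-hazards model on a survival table
#'
#' Thin, validated wrapper around the Efron-tie-corrected partial-likelihood
#' fit: continuous covariates are standardised first (so hazard ratios read
#' per SD), the fit is checked for events and for separation, and the
#' result carries hazard ratios with Wald 95% CIs, AIC and Harrell's
#' c-index.
#'
#' @param table Data frame with `time` (> 0), `event` (0/1) and covariate
#'   columns.
#' @param covariates Character vector of covariate column names.
#' @return A `cox_fit`: `coefficients` tibble (term, estimate, se, hr,
#'   ci_lo, ci_hi, p), `loglik`, `aic`, `c_index`, `n`, `n_events`, `fit`.
#' @export
fit_cox <- function(table, covariates) {
  stopifnot(all(c("time", "event") %in% names(table)))
  if (any(table$time <= 0)) abort("survival times must be positive")
  if (sum(table$event) < 1) abort("no events in the survival table")
  df <- as.data.frame(table)[c("time", "event", covariates)]
  for (cv in covariates) {
    x <- df[[cv]]
    if (length(unique(x)) < 2) abort(sprintf("constant covariate '%s'", cv))
    if (!all(x %in% c(0, 1))) df[[cv]] <- (x - mean(x)) / sd(x)
  }
  fml <- as.formula(paste("survival::Surv(time, event) ~",
                          paste(sprintf("`%s`", covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "efron")
  if (any(abs(coef(fit)) > 50))
    abort("Cox fit did not converge (separation: |coefficient| exploding)")
  sm <- summary(fit)
  co <- sm$coefficients
  conc <- survival::concordance(fit)
  structure(list(
    coefficients = tibble::tibble(
      term = covariates,
      estimate = co[, "coef"], se = co[, "se(coef)"],
      hr = exp(co[, "coef"]),
      ci_lo = exp(co[, "coef"] - qnorm(0.975) * co[, "se(coef)"]),
      ci_hi = exp(co[, "coef"] + qnorm(0.975) * co[, "se(coef)"]),
      p = co[, "Pr(>|z|)"]),
    loglik = fit$loglik[2],
    aic = 2 * length(coef(fit)) - 2 * fit$loglik[2],
    c_index = as.numeric(conc$concordance),
    n = nrow(df), n_events = sum(df$event),
    fit = fit),
    class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n=%d, events=%d, AIC=%.1f, c-index=%.3f\n",
              x$n, x$n_events, x$aic, x$c_index))
  print(x$coefficients)
  invisible(x)
}

#' Harrell's concordance index of a risk score
#'
#' Probability that, over usable pairs, the higher-risk subject has the
#' earlier event; 1 for a score that perfectly orders event times, 0.5 for
#' an uninformative score.
#'
#' @param time,event Survival outcome.
#' @param risk Higher values = higher hazard.
#' @return Concordance between 0 and 1.
#' @export
concordance_index <- function(time, event, risk) {
  df <- data.frame(time = time, event = event, risk = risk)
  cf <- survival::concordance(survival::Surv(time, event) ~ risk, data = df,
                              reverse = TRUE)
  as.numeric(cf$concordance)
}

#' Efron partial log-likelihood (reference implementation)
#'
#' Direct evaluation of the Efron-corrected Cox partial log-likelihood at a
#' coefficient vector; used as an independent oracle against the Newton
#' fit and exported for diagnostics.
#'
#' @param beta Coefficient vector.
#' @param time,event,X Survival data (X: n x p covariate matrix).
#' @return Log partial likelihood (scalar).
#' @export
cox_partial_loglik <- function(beta, time, event, X) {
  X <- as.matrix(X)
  eta <- as.numeric(X %*% beta)
  risk <- exp(eta)
  ll <- 0
  for (tt in sort(unique(time[event == 1]))) {
    D <- which(time == tt & event == 1)
    Rset <- which(time >= tt)
    d <- length(D)
    sum_r <- sum(risk[Rset])
    sum_d <- sum(risk[D])
    ll <- ll + sum(eta[D])
    for (l in seq_len(d) - 1)
      ll <- ll - log(sum_r - l / d * sum_d)
  }
  ll
}

#' Compare two Cox models on the same subjects
#'
#' AIC (`2k - 2 logPL`; lower wins) and Harrell's concordance over usable
#' pairs (higher wins), the standard comparison between a volume-based and
#' a thickness-shape-based hazard model.
#'
#' @param fit_a,fit_b `cox_fit` objects fitted to the same subjects and
#'   outcome.
#' @param labels Length-2 model labels for the report.
#' @return A `cox_comparison` tibble (one row per model) with a `winner`
#'   attribute per criterion.
#' @export
compare_models <- function(fit_a, fit_b, labels = c("model_a", "model_b")) {
  if (fit_a$n != fit_b$n || fit_a$n_events != fit_b$n_events)
    abort("models were fitted on different subject sets")
  tbl <- tibble::tibble(
    model = labels,
    n_covariates = c(nrow(fit_a$coefficients), nrow(fit_b$coefficients)),
    loglik = c(fit_a$loglik, fit_b$loglik),
    aic = c(fit_a$aic, fit_b$aic),
    c_index = c(fit_a$c_index, fit_b$c_index))
  attr(tbl, "winner") <- list(
    aic = labels[which.min(tbl$aic)],
    c_index = labels[which.max(tbl$c_index)])
  class(tbl) <- c("cox_comparison", class(tbl))
  tbl
}

#' Volume model vs thickness-shape model survival study
#'
#' Fits the two competing hazard models the pipeline is built to compare:
#' the *volume model* (adjustment covariates + total shell volume) and the
#' *thickness model*, which replaces volume with the first `n_pcs` sparse-PC
#' scores of the thickness matrix. Total-muscle covariates are refused in
#' the thickness model (correlated with the PCs by construction). BH-FDR is
#' applied across each model's hazard-ratio p values; fewer than 10 events
#' per covariate triggers a warning, not an error.
#'
#' @param outcomes Tibble: `subject_id`, `time`, `event`.
#' @param covariates Tibble of adjustment covariates keyed by `subject_id`,
#'   including a `volume` column (e.g. total shell volume in litres).
#' @param pc_model A fitted [fit_spca()] model.
#' @param thickness The [cohort_matrix()] the scores come from (rows keyed
#'   like `outcomes`).
#' @param adjustment Character vector of adjustment covariate names.
#' @param n_pcs Number of PC scores in the thickness model (4 mirrors the
#'   headline model; 25 the extended variant).
#' @return A `survival_study`: `fit_volume`, `fit_thickness`, `comparison`,
#'   and `hr_table` (both models' HRs with FDR-adjusted q values).
#' @export
run_survival_study <- function(outcomes, covariates, pc_model, thickness,
                               adjustment = character(), n_pcs = 4L) {
  if (any(grepl("muscle", adjustment, ignore.case = TRUE)))
    abort("total-muscle covariates are excluded from the thickness model (correlated with PCs)")
  n_pcs <- min(n_pcs, pc_model$k)
  scores <- spca_transform(pc_model, thickness)
  scn <- paste0("PC", seq_len(n_pcs))
  sc <- as.data.frame(scale(scores[, seq_len(n_pcs), drop = FALSE]))
  names(sc) <- scn
  sc$subject_id <- thickness$subject_ids
  tbl <- dplyr::inner_join(outcomes, covariates, by = "subject_id")
  tbl <- dplyr::inner_join(tbl, tibble::as_tibble(sc), by = "subject_id")
  if (nrow(tbl) < nrow(outcomes))
    abort("PC scores or covariates missing for some outcome subjects")
  vol_cov <- c(adjustment, "volume")
  thk_cov <- c(adjustment, scn)
  if (sum(tbl$event) < 10 * max(length(vol_cov), length(thk_cov)))
    warning("fewer than 10 events per covariate; hazard ratios may be unstable",
            call. = FALSE)
  fit_v <- fit_cox(tbl, vol_cov)
  fit_t <- fit_cox(tbl, thk_cov)
  hr <- dplyr::bind_rows(
    dplyr::mutate(fit_v$coefficients, model = "volume", .before = 1),
    dplyr::mutate(fit_t$coefficients, model = "thickness", .before = 1))
  hr <- dplyr::mutate(dplyr::group_by(hr, .data$model),
                      q = p.adjust(.data$p, method = "BH"))
  hr <- dplyr::ungroup(hr)
  structure(list(
    fit_volume = fit_v, fit_thickness = fit_t,
    comparison = compare_models(fit_v, fit_t, labels = c("volume", "thickness")),
    hr_table = hr),
    class = "survival_study")
}

#' @export
print.survival_study <- function(x, ...) {
  print(x$comparison)
  w <- attr(x$comparison, "winner")
  cat(sprintf("winner: AIC -> %s, c-index -> %s\n", w$aic, w$c_index))
  invisible(x)
}
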