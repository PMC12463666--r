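test_that("a 6-observation no-ties fit matches the grid-search partial-likelihood oracle", {
  t6 <- c(2.1, 3.7, 1.2, 5.5, 4.1, 0.8)
  e6 <- c(1, 1, 1, 0, 1, 1)
  x6 <- c(0.5, -1.2, 0.3, 0.9, -0.4, 1.1)
  fit <- fit_cox(tibble::tibble(time = t6, event = e6, x = x6), "x")
  xs <- (x6 - mean(x6)) / sd(x6)
  grid <- seq(-3, 3, by = 1e-4)
  ll <- vapply(grid, function(b) cox_partial_loglik(b, t6, e6, matrix(xs)), 0)
  expect_lt(abs(fit$coefficients$estimate - grid[which.max(ll)]), 1e-4)
  # partial likelihood at beta-hat beats beta = 0 (null model)
  expect_gt(fit$loglik, cox_partial_loglik(0, t6, e6, matrix(xs)) - 1e-12)
})

test_that("a planted hazard ratio of 2 is recovered at n = 2000", {
  set.seed(91)
  x <- rbinom(2000, 1, 0.5)
  raw <- rexp(2000, rate = 0.1 * 2^x)
  tbl <- tibble::tibble(time = pmin(raw, 15), event = as.integer(raw <= 15), g = x)
  fit <- fit_cox(tbl, "g")
  expect_gt(fit$coefficients$hr, 1.8)
  expect_lt(fit$coefficients$hr, 2.2)
})

test_that("Wald CIs cover the null for an independent covariate", {
  set.seed(92)
  covered <- replicate(50, {
    n <- 150
    tbl <- tibble::tibble(time = rexp(n, 0.2), event = rep(1L, n), x = rnorm(n))
    ci <- fit_cox(tbl, "x")$coefficients
    ci$ci_lo <= 1 && ci$ci_hi >= 1
  })
  expect_gte(mean(covered), 0.9)
})

test_that("coefficients are invariant to a common time rescaling", {
  set.seed(93)
  n <- 300
  tbl <- tibble::tibble(time = rexp(n, 0.2), event = rbinom(n, 1, 0.8), x = rnorm(n))
  f1 <- fit_cox(tbl, "x")
  tbl2 <- dplyr::mutate(tbl, time = time * 37.5)
  f2 <- fit_cox(tbl2, "x")
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate, tolerance = 1e-8)
})

test_that("degenerate survival tables are rejected", {
  expect_error(fit_cox(tibble::tibble(time = c(1, 2), event = c(0, 0), x = c(1, 2)), "x"),
               "no events")
  expect_error(fit_cox(tibble::tibble(time = c(1, 2), event = c(1, 1), x = c(1, 1)), "x"),
               "constant")
  expect_error(fit_cox(tibble::tibble(time = c(-1, 2), event = c(1, 1), x = c(1, 2)), "x"),
               "positive")
})

test_that("c-index is 1 for a perfect risk score and ~0.5 for noise", {
  set.seed(94)
  n <- 200
  risk <- rnorm(n)
  time <- exp(-risk)           # risk order = event order exactly
  expect_equal(concordance_index(time, rep(1L, n), risk), 1.0)
  noise_c <- replicate(20, concordance_index(time, rep(1L, n), rnorm(n)))
  se <- sd(noise_c) / sqrt(20)
  expect_lt(abs(mean(noise_c) - 0.5), 3 * se + 0.01)
})

test_that("adding a pure-noise covariate raises AIC in expectation", {
  set.seed(95)
  diffs <- replicate(25, {
    n <- 120
    x <- rnorm(n)
    raw <- rexp(n, rate = 0.2 * exp(0.5 * x))
    tbl <- tibble::tibble(time = pmin(raw, 12), event = as.integer(raw <= 12),
                          x = x, junk = rnorm(n))
    fit_cox(tbl, c("x", "junk"))$aic - fit_cox(tbl, "x")$aic
  })
  expect_gt(mean(diffs), 0)
})

test_that("model comparison reports AIC and c-index winners on matched subjects", {
  set.seed(96)
  n <- 400
  x <- rnorm(n)
  raw <- rexp(n, rate = 0.1 * exp(0.7 * x))
  tbl <- tibble::tibble(time = pmin(raw, 20), event = as.integer(raw <= 20),
                        x = x, z = rnorm(n))
  fa <- fit_cox(tbl, "x")
  fb <- fit_cox(tbl, "z")
  cmp <- compare_models(fa, fb, labels = c("signal", "noise"))
  expect_equal(attr(cmp, "winner")$aic, "signal")
  expect_equal(attr(cmp, "winner")$c_index, "signal")
  expect_equal(cmp$aic, c(fa$aic, fb$aic))

  fa2 <- fit_cox(tbl[1:300, ], "x")
  expect_error(compare_models(fa, fa2), "different subject sets")
})

planted_pc_study <- function(seed, hazard_via = c("pc2", "volume", "none"),
                             sparsity = 30) {
  hazard_via <- match.arg(hazard_via)
  spec <- cohort_spec(n_subjects = 250L, seed = seed, grid_shape = c(72L, 72L, 72L),
                      effect_regions = list(
                        effect_region(c(0, 0, 1), 0.9, "vat_l", 2),
                        effect_region(c(1, 0, 0), 0.8, "hgs", -1.5)))
  ch <- generate_cohort(spec, template_subdivisions = 2)
  model <- fit_spca(ch$thickness, k = 4, sparsity = sparsity)
  sc <- scale(model$scores)
  colnames(sc) <- paste0("PC", 1:4)
  vol <- scale(rowMeans(ch$thickness$values))[, 1]
  gen <- cbind(as.data.frame(sc), volume = vol)
  spec$survival <- switch(hazard_via,
    pc2 = list(baseline_hazard = 0.03, log_hr = c(PC2 = log(2)), censor_time = 12),
    volume = list(baseline_hazard = 0.03, log_hr = c(volume = log(2)), censor_time = 12),
    none = list(baseline_hazard = 0.03, log_hr = c(PC1 = 0), censor_time = 12))
  surv <- generate_survival(spec, gen)
  covs <- ch$covariates
  covs$volume <- rowMeans(ch$thickness$values)
  run_survival_study(surv, covs, model, ch$thickness,
                     adjustment = c("age", "height"), n_pcs = 4)
}

test_that("the thickness model wins when hazard acts through a PC score", {
  st <- planted_pc_study(101, "pc2")
  w <- attr(st$comparison, "winner")
  expect_equal(w$aic, "thickness")
  expect_equal(w$c_index, "thickness")
  hr <- st$hr_table
  expect_lt(hr$q[hr$model == "thickness" & hr$term == "PC2"], 0.05)
})

test_that("the volume model wins on AIC when hazard acts through volume", {
  wins <- vapply(1:5, function(s) {
    st <- planted_pc_study(110 + s, "volume")
    attr(st$comparison, "winner")$aic == "volume"
  }, NA)
  expect_gte(sum(wins), 4)
})

test_that("muscle covariates are refused in the thickness model", {
  expect_error(run_survival_study(NULL, NULL, NULL, NULL,
                                  adjustment = c("age", "total_muscle")),
               "muscle")
})
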