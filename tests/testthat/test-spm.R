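test_that("standardisation z-scores continuous columns and records the inverse", {
  dat <- tibble::tibble(x = c(1, 2, 3), b = c(0, 1, 1))
  des <- design_matrix(dat, c("x", "b"))
  Y <- matrix(c(4, 6, 8, 1, 1, 2), nrow = 3)
  std <- standardize(des, Y)
  expect_equal(unname(std$design$X[, "x"]), c(-1, 0, 1))
  expect_equal(unname(std$design$X[, "b"]), c(0, 1, 1))
  expect_equal(colMeans(std$response), c(0, 0))
  expect_equal(apply(std$response, 2, sd), c(1, 1))
  # round trip
  back <- sweep(sweep(std$response, 2, std$y_scale, "*"), 2, std$y_center, "+")
  expect_equal(back, Y, tolerance = 1e-12)
  xb <- std$design$X[, "x"] * std$x_scale["x"] + std$x_center["x"]
  expect_equal(unname(xb), dat$x, tolerance = 1e-12)

  des0 <- structure(list(X = cbind(`(intercept)` = 1, x = c(2, 2, 2)),
                         continuous = c(`(intercept)` = FALSE, x = TRUE),
                         names = c("(intercept)", "x")),
                    class = "design_matrix")
  expect_error(standardize(des0, Y), "zero-variance.*'x'")
})

test_that("rank-deficient designs are rejected with the collinear columns named", {
  dat <- tibble::tibble(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8))
  expect_error(design_matrix(dat, c("a", "b")), "collinear.*b")
})

test_that("vertex-wise OLS equals per-vertex lm and is order-invariant", {
  set.seed(51)
  n <- 40; V <- 12
  dat <- tibble::tibble(x = rnorm(n), g = rbinom(n, 1, 0.4))
  des <- design_matrix(dat, c("x", "g"))
  Y <- matrix(rnorm(n * V), n, V)
  fit <- vertexwise_ols(Y, des)
  for (v in c(1, 5, 12)) {
    lf <- summary(lm(Y[, v] ~ dat$x + dat$g))
    expect_equal(unname(fit$beta[, v]), unname(coef(lf)[, 1]), tolerance = 1e-10)
    expect_equal(unname(fit$t[, v]), unname(coef(lf)[, 3]), tolerance = 1e-8)
  }
  perm <- sample(n)
  des2 <- des; des2$X <- des$X[perm, ]
  fit2 <- vertexwise_ols(Y[perm, ], des2)
  expect_equal(fit2$beta, fit$beta, tolerance = 1e-12)
})

test_that("a noiseless planted model is recovered exactly with large finite t", {
  n <- 30
  x <- rnorm(n)
  des <- design_matrix(tibble::tibble(x = x), "x", binary = character())
  Y <- cbind(0.5 * x, 0.5 * x + rnorm(n, 0, 0.1))
  fit <- vertexwise_ols(Y, des)
  expect_equal(unname(fit$beta["x", 1]), 0.5, tolerance = 1e-12)
  expect_true(is.finite(fit$t["x", 1]))
  expect_gt(fit$t["x", 1], 1e5)
})

test_that("TFCE reproduces the hand-worked 3-vertex path example exactly", {
  edges <- rbind(c(1L, 2L), c(2L, 3L))
  cfg <- spm_config(tfce_E = 0.5, tfce_H = 2, n_steps = 10)
  cfg$n_steps <- 2L # dh = h_max / n_steps = 1
  out <- tfce_enhance(c(1, 2, 0), edges, config = cfg)
  expect_equal(out, c(sqrt(2), sqrt(2) + 4, 0), tolerance = 1e-9)
})

test_that("TFCE of a non-positive map is zero and non-finite maps error", {
  edges <- rbind(c(1L, 2L))
  expect_equal(tfce_enhance(c(0, 0), edges), c(0, 0))
  expect_equal(tfce_enhance(c(-1, -3), edges), c(0, 0))
  expect_error(tfce_enhance(c(1, NA), edges), "non-finite")
})

test_that("TFCE matches a brute-force threshold loop on random graphs", {
  set.seed(52)
  for (rep in 1:50) {
    nv <- sample(5:30, 1)
    edges <- random_graph(nv)
    stat <- round(pmax(rnorm(nv, 0.5, 1), 0), 3)
    if (max(stat) == 0) stat[1] <- 1
    cfg <- spm_config(n_steps = 17L)
    got <- tfce_enhance(stat, edges, config = cfg)
    want <- bf_tfce(stat, edges, E = 0.5, H = 2, n_steps = 17L)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("TFCE with area-weighted extents matches the weighted brute force", {
  set.seed(53)
  nv <- 20
  edges <- random_graph(nv)
  stat <- pmax(rnorm(nv, 0.5, 1), 0)
  w <- runif(nv, 0.5, 2)
  cfg <- spm_config(n_steps = 13L, extent_mode = "area_weighted")
  got <- tfce_enhance(stat, edges, areas = w, config = cfg)
  want <- bf_tfce(stat, edges, E = 0.5, H = 2, n_steps = 13L, w = w)
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("TFCE is monotone under scaling and converges with step refinement", {
  set.seed(54)
  mesh <- icosphere(2, 1)
  edges <- mesh_edges(mesh)
  nv <- n_vertices(mesh)
  # smooth random field
  base <- rnorm(nv)
  adj <- vertex_adjacency(mesh)
  for (i in 1:6) base <- vapply(seq_len(nv), function(v) mean(base[c(v, adj[[v]])]), 0)
  stat <- pmax(base * 10, 0)
  t1 <- tfce_enhance(stat, edges, config = spm_config(n_steps = 100L))
  t2 <- tfce_enhance(2 * stat, edges, config = spm_config(n_steps = 100L))
  expect_true(all(t2 >= t1 - 1e-12))
  t4 <- tfce_enhance(stat, edges, config = spm_config(n_steps = 200L))
  rel <- abs(t4[stat > 0] - t1[stat > 0]) / pmax(t1[stat > 0], 1e-12)
  expect_lt(median(rel), 0.02)
})

test_that("BH step-up matches the hand computation", {
  mask <- bh_fdr(c(0.01, 0.02, 0.04, 0.50), q = 0.05)
  expect_equal(mask, c(TRUE, TRUE, FALSE, FALSE))
  expect_false(any(bh_fdr(rep(1, 10), 0.05)))
  m <- 8
  expect_true(all(bh_fdr(rep(0.05 / m, m), 0.05)))
})

test_that("permutation p values are bounded, deterministic, and saturate on strong effects", {
  set.seed(55)
  spec <- cohort_spec(n_subjects = 80L,
                      effect_regions = list(effect_region(c(1, 0, 0), acos(0.6), "vat_l",
                                                          beta_for_standardized_effect(cohort_spec(), 0.6))),
                      seed = 21L)
  ch <- generate_cohort(spec, template_subdivisions = 2)
  des <- design_matrix(ch$covariates, c("age", "vat_l"))
  std <- standardize(des, ch$thickness)
  edges <- mesh_edges(ch$template)
  cfg <- spm_config(n_permutations = 199L, seed = 7L)
  pi1 <- permutation_inference(std$response, std$design, "vat_l", edges, config = cfg)
  pi2 <- permutation_inference(std$response, std$design, "vat_l", edges, config = cfg)
  expect_identical(pi1$p_pos, pi2$p_pos)
  expect_true(all(pi1$p_pos >= 1 / 200 & pi1$p_pos <= 1))
  expect_true(all(pi1$p_neg >= 1 / 200 & pi1$p_neg <= 1))
  gt <- ch$ground_truth$region_mask$vat_l
  expect_equal(min(pi1$p_pos[gt]), 1 / 200)
  expect_error(
    permutation_inference(std$response, std$design, "nope", edges, config = cfg),
    "not in design")
})

test_that("a planted regional effect is recovered with the right area and size", {
  spec <- cohort_spec(
    n_subjects = 200L, seed = 31L,
    effect_regions = list(effect_region(c(1, 0, 0), acos(0.6), "vat_l",
                                        beta_for_standardized_effect(cohort_spec(), 0.5))))
  ch <- generate_cohort(spec, template_subdivisions = 3)
  des <- design_matrix(ch$covariates, c("age", "vat_l"))
  spm <- run_spm(ch$thickness, des, spm_config(n_permutations = 199L, seed = 8L))
  gt <- ch$ground_truth$region_mask$vat_l
  det <- spm$maps$vat_l$sig_pos
  dice <- 2 * sum(gt & det) / (sum(gt) + sum(det))
  expect_gt(dice, 0.8)
  expect_lt(abs(median(spm$maps$vat_l$beta_std[det]) - 0.5), 0.05)
  smry <- tidy(spm)
  area <- smry$significance_area_pct[smry$covariate == "vat_l" & smry$sign == "positive"]
  expect_gt(area, 15); expect_lt(area, 26)
  # null covariate stays quiet
  area_null <- smry$significance_area_pct[smry$covariate == "age"]
  expect_true(all(area_null <= 1))
})

test_that("summary of a full constant-beta mask reports median c, IQR 0, area 100%", {
  res <- structure(list(
    maps = list(x = list(beta_std = rep(2, 10), beta_mm = rep(4, 10),
                         sig_pos = rep(TRUE, 10), sig_neg = rep(FALSE, 10))),
    config = spm_config(), areas = rep(1, 10)), class = "spm_result")
  smry <- summarize_spm(res)
  pos <- smry[smry$sign == "positive", ]
  expect_equal(pos$median_beta_std, 2)
  expect_equal(pos$iqr_beta_std, 0)
  expect_equal(pos$significance_area_pct, 100)
  neg <- smry[smry$sign == "negative", ]
  expect_equal(neg$significance_area_pct, 0)
  expect_true(is.na(neg$median_beta_std))
})
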