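test_that("concentric spheres r=70/50 give 20 mm thickness everywhere", {
  outer <- icosphere(4, 70)
  inner <- icosphere(4, 50)
  expect_gt(nrow(inner$faces), 1000)
  tf <- compute_thickness(outer, inner, subject_id = "S1")
  expect_true(all(abs(tf$values - 20) / 20 < 0.01))
})

test_that("outer mesh equal to inner mesh gives zero thickness", {
  m <- icosphere(3, 30)
  tf <- compute_thickness(m, m)
  expect_true(all(tf$values < 1e-9))
})

test_that("coaxial capped cylinders give the radial gap on the mid band", {
  cyl <- function(r, h, nseg = 96, nz = 40) {
    th <- seq(0, 2 * pi, length.out = nseg + 1)[-(nseg + 1)]
    zs <- seq(-h / 2, h / 2, length.out = nz)
    v <- cbind(r * cos(rep(th, nz)), r * sin(rep(th, nz)), rep(zs, each = nseg))
    f <- NULL
    for (iz in seq_len(nz - 1)) {
      base <- (iz - 1) * nseg
      i1 <- base + seq_len(nseg)
      i2 <- base + c(2:nseg, 1)
      f <- rbind(f, cbind(i1, i2, i2 + nseg), cbind(i1, i2 + nseg, i1 + nseg))
    }
    # caps: fan to centre points
    nc <- nrow(v)
    v <- rbind(v, c(0, 0, -h / 2), c(0, 0, h / 2))
    bot <- seq_len(nseg); top <- (nz - 1) * nseg + seq_len(nseg)
    f <- rbind(f, cbind(bot, c(bot[-1], bot[1]), nc + 1),
               cbind(top, c(top[-1], top[1]), nc + 2))
    surface_mesh(v, f, clean = FALSE)
  }
  outer <- cyl(30, 120)
  inner <- cyl(20, 120)
  tf <- compute_thickness(outer, inner)
  mid <- abs(outer$vertices[, 3]) < 20 & sqrt(rowSums(outer$vertices[, 1:2]^2)) > 29
  expect_true(all(abs(tf$values[mid] - 10) < 0.1))
})

test_that("thickness is invariant under a common rigid transform", {
  outer <- icosphere(3, 65)
  inner <- icosphere(3, 48)
  t0 <- compute_thickness(outer, inner)$values
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  mv <- function(m) { m$vertices <- sweep(m$vertices %*% t(R), 2, c(3, -2, 7), "+"); m }
  t1 <- compute_thickness(mv(outer), mv(inner))$values
  expect_lt(max(abs(t1 - t0)), 1e-6)
})

test_that("nested-ellipsoid thickness never exceeds the maximum radial gap", {
  set.seed(41)
  for (rep in 1:4) {
    ro <- runif(3, 50, 70)
    ri <- ro - runif(3, 5, 20)
    mko <- icosphere(3, 1); U <- mko$vertices
    r_out <- 1 / sqrt(rowSums(sweep(U^2, 2, ro^2, "/")))
    r_in <- 1 / sqrt(rowSums(sweep(U^2, 2, ri^2, "/")))
    outer <- surface_mesh(U * r_out, mko$faces, clean = FALSE)
    inner <- surface_mesh(U * r_in, mko$faces, clean = FALSE)
    tf <- compute_thickness(outer, inner)$values
    expect_true(all(tf <= max(r_out - r_in) + 1e-9))
  }
})

test_that("QC filter applies the 154 mm rule and percentile rule correctly", {
  mk_field <- function(id, mx) {
    mesh <- icosphere(0, 1)
    vals <- rep(mx / 2, 12); vals[1] <- mx
    structure(list(values = vals, mesh = mesh, unit = "mm",
                   subject_id = id, visit = 1L),
              class = c("thickness_field", "vertex_field"))
  }
  fields <- list(mk_field("a", 80), mk_field("b", 120), mk_field("c", 160))
  qc <- qc_filter(fields, max_thickness_mm = 154)
  expect_setequal(qc$kept, c("a", "b"))
  expect_equal(qc$excluded, "c")
  expect_equal(unique(qc$report$threshold_mm), 154)

  qc2 <- qc_filter(fields, max_thickness_mm = 1000)
  expect_length(qc2$excluded, 0)

  f4 <- list(mk_field("a", 10), mk_field("b", 20), mk_field("c", 30), mk_field("d", 40))
  qc3 <- qc_filter(f4, percentile = 50)
  # linear-interpolation 50th percentile of {10,20,30,40} is 25
  expect_setequal(qc3$kept, c("a", "b"))
  expect_setequal(qc3$excluded, c("c", "d"))

  expect_error(qc_filter(fields, percentile = 101), "strictly between")
  expect_error(qc_filter(fields), "exactly one")
  expect_error(qc_filter(fields, max_thickness_mm = 100, percentile = 50), "exactly one")
})

test_that("lipodystrophy rule uses strict sex-specific FMR cut-offs", {
  expect_true(derive_lipodystrophy(1.3, "F"))
  expect_false(derive_lipodystrophy(1.3, "M"))
  expect_false(derive_lipodystrophy(1.2, "F"))
  expect_false(derive_lipodystrophy(1.7, "M"))
  expect_true(derive_lipodystrophy(1.71, "M"))
  expect_equal(derive_lipodystrophy(c(1.3, 1.3), c("F", "M")), c(TRUE, FALSE))
  expect_error(derive_lipodystrophy(1.0, "X"), "unknown sex")
  expect_error(derive_lipodystrophy(-0.1, "F"), "non-negative")
})

test_that("stacking thickness fields preserves order, shape and template", {
  tmpl <- icosphere(2, 40)
  mkf <- function(id, val) structure(
    list(values = rep(val, n_vertices(tmpl)), mesh = tmpl, unit = "mm",
         subject_id = id, visit = 1L),
    class = c("thickness_field", "vertex_field"))
  cm <- stack_cohort(list(mkf("s1", 1), mkf("s2", 2), mkf("s3", 3)))
  expect_equal(dim(cm$values), c(3L, n_vertices(tmpl)))
  expect_equal(cm$subject_ids, c("s1", "s2", "s3"))
  expect_equal(unname(cm$values[2, 1]), 2)

  one <- stack_cohort(list(mkf("solo", 7)))
  expect_equal(dim(one$values), c(1L, n_vertices(tmpl)))
  expect_true(all(one$values == 7))

  other <- icosphere(1, 40)
  bad <- structure(list(values = rep(1, n_vertices(other)), mesh = other,
                        unit = "mm", subject_id = "x", visit = 1L),
                   class = c("thickness_field", "vertex_field"))
  expect_error(stack_cohort(list(mkf("s1", 1), bad)), "different templates")
})
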