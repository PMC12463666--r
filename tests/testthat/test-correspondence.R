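# Bumpy scalene ellipsoid: asymmetric enough for unambiguous alignment.
bumpy_ellipsoid <- function(subdiv = 3, radii = c(30, 22, 40)) {
  sph <- icosphere(subdiv, 1)
  U <- sph$vertices
  r <- 1 / sqrt((U[, 1] / radii[1])^2 + (U[, 2] / radii[2])^2 + (U[, 3] / radii[3])^2)
  # two odd bump terms kill every rotational symmetry of the ellipsoid
  r <- r * (1 + 0.1 * U[, 1] * U[, 3]^2 + 0.05 * U[, 2]^2 * U[, 3])
  surface_mesh(U * r, sph$faces, clean = FALSE)
}

rot_z <- function(theta) {
  rbind(c(cos(theta), -sin(theta), 0), c(sin(theta), cos(theta), 0), c(0, 0, 1))
}

test_that("rigid ICP inverts a planted rotation + translation", {
  mesh <- bumpy_ellipsoid()
  moved <- mesh
  moved$vertices <- sweep(mesh$vertices %*% t(rot_z(30 * pi / 180)), 2, c(5, 0, 0), "+")
  al <- rigid_align(moved, mesh)
  rmsd <- sqrt(mean(rowSums((al$aligned$vertices - mesh$vertices)^2)))
  expect_lt(rmsd, 0.01)
  # the recovered rotation inverts the planted one
  expect_equal(al$transform[1:3, 1:3] %*% rot_z(30 * pi / 180), diag(3),
               tolerance = 1e-4)
})

test_that("rigid ICP on identical meshes is the identity", {
  mesh <- bumpy_ellipsoid()
  al <- rigid_align(mesh, mesh)
  expect_lt(max(abs(al$transform - diag(4))), 1e-6)
  expect_lt(al$objective, 1e-12)
})

test_that("rigid ICP on a radially noisy sphere stays within the noise scale", {
  set.seed(31)
  sph <- icosphere(3, 40)
  noisy <- sph
  r <- sqrt(rowSums(sph$vertices^2))
  noise_sd <- 0.5
  noisy$vertices <- sph$vertices * (r + rnorm(length(r), 0, noise_sd)) / r
  al <- rigid_align(noisy, sph)
  expect_lt(sqrt(al$objective), noise_sd * sqrt(2))
})

test_that("affine ICP recovers anisotropic scaling within 1%", {
  mesh <- bumpy_ellipsoid()
  scaled <- mesh
  scaled$vertices <- mesh$vertices %*% diag(c(1.2, 0.9, 1.0))
  af <- affine_align(mesh, scaled)
  expect_equal(diag(af$transform)[1:3], c(1.2, 0.9, 1.0), tolerance = 0.01)
})

test_that("affine ICP from identity on identical meshes is the identity affine", {
  mesh <- bumpy_ellipsoid()
  af <- affine_align(mesh, mesh, initial = diag(4))
  expect_lt(max(abs(af$transform - diag(4))), 1e-6)
})

test_that("affine objective never exceeds its rigid initialisation", {
  set.seed(32)
  mesh <- bumpy_ellipsoid()
  other <- bumpy_ellipsoid(radii = c(33, 20, 38))
  rig <- rigid_align(mesh, other)
  af <- affine_align(mesh, other, initial = rig$transform)
  expect_lte(af$objective, rig$objective + 1e-12)
})

test_that("template of N copies of one mesh is that mesh", {
  mesh <- bumpy_ellipsoid()
  tm <- build_template(list(mesh, mesh, mesh), reference_index = 1L)
  expect_lt(max(abs(tm$mesh$vertices - mesh$vertices)), 1e-6)
  expect_equal(n_vertices(tm$mesh), n_vertices(mesh))
})

test_that("template of concentric spheres r=40 and r=60 is the mean shape r~50", {
  tm <- build_template(list(icosphere(3, 40), icosphere(3, 60)), 1L)
  radii <- sqrt(rowSums(tm$mesh$vertices^2))
  expect_true(all(abs(radii - 50) < 0.5))
})

test_that("template construction needs at least two meshes", {
  expect_error(build_template(list(icosphere(1, 10))), "at least 2")
})

test_that("template propagation is an identity on the template itself", {
  mesh <- bumpy_ellipsoid()
  pr <- propagate_template(mesh, mesh)
  expect_lt(max(abs(pr$resampled$vertices - mesh$vertices)), 1e-9)
  expect_true(all(pr$correspondence$b1 >= 0 & pr$correspondence$b2 >= 0 &
                    pr$correspondence$b3 >= 0))
  expect_equal(pr$correspondence$b1 + pr$correspondence$b2 + pr$correspondence$b3,
               rep(1, n_vertices(mesh)), tolerance = 1e-9)
})

test_that("propagation yields template topology for any subject", {
  tmpl <- icosphere(3, 50)
  subj <- icosphere(4, 55)
  pr <- propagate_template(tmpl, subj)
  expect_equal(n_vertices(pr$resampled), n_vertices(tmpl))
  expect_identical(pr$resampled$faces, tmpl$faces)
  radii <- sqrt(rowSums(pr$resampled$vertices^2))
  expect_true(all(radii > 54.9 & radii < 55.1))
})

test_that("resampling is exactly idempotent on flat-limit input and curvature-bounded otherwise", {
  # when the subject already is the template surface, re-resampling is exact
  tmpl <- icosphere(3, 50)
  pr0 <- propagate_template(tmpl, tmpl)
  pr0b <- propagate_template(tmpl, pr0$resampled)
  expect_lt(max(abs(pr0b$resampled$vertices - pr0$resampled$vertices)), 1e-9)

  # on a curved subject the second projection lands on chord faces of the
  # first resampling, so vertices drift at sagitta (second, curvature) order:
  # far below the template edge length, vanishing with refinement
  subj <- bumpy_ellipsoid(subdiv = 4, radii = c(52, 49, 55))
  drift_at <- function(subdiv) {
    tm <- icosphere(subdiv, 50)
    p1 <- propagate_template(tm, subj)
    p2 <- propagate_template(tm, p1$resampled)
    sqrt(rowSums((p2$resampled$vertices - p1$resampled$vertices)^2))
  }
  d3 <- drift_at(3)
  edge3 <- median(sqrt(rowSums((icosphere(3, 50)$vertices[mesh_edges(icosphere(3, 50))[, 1], ] -
                                icosphere(3, 50)$vertices[mesh_edges(icosphere(3, 50))[, 2], ])^2)))
  expect_lt(median(d3), 0.05 * edge3)
  d4 <- drift_at(4)
  expect_lt(median(d4), median(d3)) # refinement shrinks the drift
})
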