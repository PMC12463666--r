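#' Rigid and affine mesh alignment by iterative closest point
#'
#' `rigid_align()` registers `moving` to `fixed` by ICP: at each iteration
#' every moving vertex is matched to its nearest fixed vertex, and the
#' rotation + translation minimising the mean squared distance to the
#' matches is solved in closed form (SVD Procrustes / Kabsch step). The
#' objective is monotone non-increasing by construction. `affine_align()`
#' runs the same loop with an unconstrained 12-parameter linear map, seeded
#' by a rigid (or user-supplied) transform; its converged objective can
#' never exceed the rigid one it starts from.
#'
#' Transforms are 4x4 homogeneous matrices acting on row vectors as
#' `x' = (T %*% c(x, 1))[1:3]`.
#'
#' @param moving,fixed [surface_mesh()] objects.
#' @param max_iterations ICP iteration cap.
#' @param tol Stop when the mean-squared-distance improvement falls below
#'   this (mm^2).
#' @param initial Optional 4x4 starting transform (affine: defaults to a
#'   fresh rigid alignment).
#' @return List with `transform` (4x4), `aligned` (transformed moving mesh)
#'   and `objective` (final mean squared nearest-point distance, mm^2).
#' @export
rigid_align <- function(moving, fixed, max_iterations = 50L, tol = 1e-8) {
  # ICP with nearest-vertex matching has local minima under large rotations;
  # restart from identity and from principal-axes alignments (all proper
  # sign combinations) and keep the best converged fit.
  inits <- c(list(diag(4)), pca_inits(moving$vertices, fixed$vertices))
  # short pilot runs rank the starts; the winner gets the full iteration budget
  pilots <- lapply(inits, function(ini)
    icp_core(moving, fixed, kind = "rigid", initial = ini,
             max_iterations = min(8L, max_iterations), tol = tol))
  best <- pilots[[which.min(vapply(pilots, `[[`, numeric(1), "objective"))]]
  icp_core(moving, fixed, kind = "rigid", initial = best$transform,
           max_iterations = max_iterations, tol = tol)
}

# candidate rigid transforms aligning principal axes of X to those of Y
pca_inits <- function(X, Y) {
  mx <- colMeans(X); my <- colMeans(Y)
  Ux <- eigen(cov(X), symmetric = TRUE)$vectors
  Uy <- eigen(cov(Y), symmetric = TRUE)$vectors
  if (det(Ux) < 0) Ux[, 3] <- -Ux[, 3]
  if (det(Uy) < 0) Uy[, 3] <- -Uy[, 3]
  signs <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  lapply(signs, function(s) {
    R <- Uy %*% diag(s) %*% t(Ux)
    T4 <- diag(4)
    T4[1:3, 1:3] <- R
    T4[1:3, 4] <- my - as.numeric(R %*% mx)
    T4
  })
}

#' @rdname rigid_align
#' @export
affine_align <- function(moving, fixed, initial = NULL,
                         max_iterations = 50L, tol = 1e-8) {
  if (is.null(initial)) initial <- rigid_align(moving, fixed)$transform
  icp_core(moving, fixed, kind = "affine", initial = initial,
           max_iterations = max_iterations, tol = tol)
}

apply_transform <- function(points, transform) {
  sweep(points %*% t(transform[1:3, 1:3]), 2, transform[1:3, 4], "+")
}

#' Apply a 4x4 homogeneous transform to a mesh
#' @param mesh A [surface_mesh()].
#' @param transform 4x4 matrix.
#' @return Transformed mesh (topology unchanged).
#' @export
transform_mesh <- function(mesh, transform) {
  mesh$vertices <- apply_transform(mesh$vertices, transform)
  mesh
}

icp_core <- function(moving, fixed, kind, initial, max_iterations, tol,
                     max_points = 1500L, max_fixed = 4000L) {
  if (n_vertices(moving) == 0 || n_vertices(fixed) == 0)
    abort("cannot align empty meshes")
  X0 <- moving$vertices
  # deterministic subsamples keep each ICP iteration O(max_points * max_fixed)
  if (nrow(X0) > max_points)
    X0 <- X0[round(seq(1, nrow(X0), length.out = max_points)), , drop = FALSE]
  F0 <- fixed$vertices
  if (nrow(F0) > max_fixed)
    F0 <- F0[round(seq(1, nrow(F0), length.out = max_fixed)), , drop = FALSE]
  fixed <- list(vertices = F0)
  Tcur <- initial
  obj_prev <- Inf
  for (it in seq_len(max_iterations)) {
    X <- apply_transform(X0, Tcur)
    nn <- cpp_nearest_vertex(X, fixed$vertices)
    Y <- fixed$vertices[nn$index, , drop = FALSE]
    obj <- mean(nn$dist^2)
    if (it == 1L && obj > obj_prev) abort("ICP failed to evaluate objective")
    if (obj_prev - obj < tol) { obj_prev <- min(obj, obj_prev); break }
    obj_prev <- obj
    Tstep <- if (kind == "rigid") procrustes_rigid(X, Y) else fit_affine(X, Y)
    Tcur <- Tstep %*% Tcur
  }
  list(transform = Tcur,
       aligned = transform_mesh(moving, Tcur),
       objective = obj_prev,
       iterations = it)
}

# Closed-form rigid transform minimising ||R x + t - y||^2 (Kabsch).
procrustes_rigid <- function(X, Y) {
  mx <- colMeans(X); my <- colMeans(Y)
  H <- crossprod(sweep(X, 2, mx), sweep(Y, 2, my))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- my - as.numeric(R %*% mx)
  T4 <- diag(4)
  T4[1:3, 1:3] <- R
  T4[1:3, 4] <- t
  T4
}

# Least-squares affine map X -> Y.
fit_affine <- function(X, Y) {
  Xh <- cbind(X, 1)
  if (qr(Xh)$rank < 4) abort("degenerate (rank-deficient) point set for affine fit")
  A <- qr.solve(Xh, Y) # 4 x 3
  T4 <- diag(4)
  T4[1:3, 1:3] <- t(A[1:3, ])
  T4[1:3, 4] <- A[4, ]
  T4
}
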