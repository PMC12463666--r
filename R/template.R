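#' Build a template surface from a set of subject meshes
#'
#' All meshes are rigid-then-affine aligned to the reference mesh; the
#' template keeps the reference topology with each vertex moved to the mean
#' of its closest points on every aligned subject surface (one averaging
#' pass). The template is purely a referencing space: vertex `v` means the
#' same location on every subject after propagation.
#'
#' @param meshes List of at least two [surface_mesh()] objects.
#' @param reference_index Which mesh supplies the template topology.
#' @param alignment `"rigid"` (default) or `"affine"` subject-to-reference
#'   alignment before averaging. Rigid preserves each subject's size, so the
#'   template is a true mean shape; affine normalises size/shear into the
#'   reference frame first.
#' @return A `template_model`: `mesh`, `reference_index`, `subject_ids`,
#'   `transforms` (per-subject 4x4 alignment into template space).
#' @export
build_template <- function(meshes, reference_index = 1L,
                           alignment = c("rigid", "affine")) {
  alignment <- match.arg(alignment)
  if (length(meshes) < 2) abort("template construction needs at least 2 meshes")
  ref <- meshes[[reference_index]]
  nsub <- length(meshes)
  transforms <- vector("list", nsub)
  acc <- matrix(0, n_vertices(ref), 3)
  for (i in seq_len(nsub)) {
    if (i == reference_index) {
      transforms[[i]] <- diag(4)
      acc <- acc + ref$vertices
      next
    }
    al <- if (alignment == "rigid") rigid_align(meshes[[i]], ref)
          else affine_align(meshes[[i]], ref)
    transforms[[i]] <- al$transform
    cp <- cpp_mesh_closest(ref$vertices, al$aligned$vertices, al$aligned$faces)
    acc <- acc + cp$point
  }
  tmesh <- ref
  tmesh$vertices <- acc / nsub
  structure(list(mesh = tmesh,
                 reference_index = reference_index,
                 subject_ids = names(meshes) %||% as.character(seq_len(nsub)),
                 transforms = transforms),
            class = "template_model")
}

#' @export
print.template_model <- function(x, ...) {
  cat(sprintf("<template_model> %d vertices, built from %d subjects\n",
              n_vertices(x$mesh), length(x$transforms)))
  invisible(x)
}

#' Propagate the template onto a subject surface
#'
#' For each template vertex the exact closest point on the subject surface
#' is found (point-to-triangle) and recorded as a (face, barycentric)
#' correspondence; the resampled subject mesh keeps the template topology
#' with vertices at those closest points, giving every subject a consistent
#' vertex count and anatomical correspondence.
#'
#' @param template A `template_model` (or bare [surface_mesh()]).
#' @param subject A [surface_mesh()] already aligned to template space.
#' @param align If `TRUE`, rigid+affine align the subject to the template
#'   first (the inverse transform is applied to map correspondences back).
#' @return List: `correspondence` (tibble: template_vertex, face, b1..b3,
#'   distance), `resampled` (subject surface with template topology, in the
#'   subject's original frame), `transform`.
#' @export
propagate_template <- function(template, subject, align = FALSE) {
  tmesh <- if (inherits(template, "template_model")) template$mesh else template
  transform <- diag(4)
  subj_aligned <- subject
  if (align) {
    al <- affine_align(subject, tmesh)
    subj_aligned <- al$aligned
    transform <- al$transform
  }
  cp <- cpp_mesh_closest(tmesh$vertices, subj_aligned$vertices, subj_aligned$faces)
  corr <- tibble::tibble(
    template_vertex = seq_len(n_vertices(tmesh)),
    face = cp$face,
    b1 = cp$bary[, 1], b2 = cp$bary[, 2], b3 = cp$bary[, 3],
    distance = cp$dist)
  pts <- cp$point
  if (align) pts <- apply_transform(pts, solve(transform))
  resampled <- surface_mesh(pts, tmesh$faces, clean = FALSE)
  list(correspondence = corr, resampled = resampled, transform = transform)
}
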