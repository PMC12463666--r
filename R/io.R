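#' Read / write voxel masks as NIfTI
#'
#' The affine encodes voxel spacing on its diagonal and the origin in its
#' translation column; round trips are voxel-exact.
#'
#' @param mask A [voxel_mask()].
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `read_mask()`: a [voxel_mask()]; `write_mask()`: `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  img <- RNifti::asNifti(mask$occupancy)
  aff <- diag(c(mask$spacing_mm, 1))
  aff[1:3, 4] <- mask$origin_mm
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  voxel_mask(array(as.integer(img != 0), dim = dim(img)),
             spacing_mm = abs(diag(aff)[1:3]),
             origin_mm = aff[1:3, 4])
}

#' Read / write triangle meshes (ASCII PLY and legacy VTK polydata)
#'
#' PLY stores geometry only; the VTK writer can attach one per-vertex scalar
#' array (e.g. a thickness field) as `POINT_DATA`.
#'
#' @param mesh A [surface_mesh()].
#' @param path Output path; format chosen by extension (`.ply` or `.vtk`).
#' @param scalars Optional named list with one numeric per-vertex vector
#'   (VTK only), e.g. `list(thickness_mm = values)`.
#' @return `read_mesh()`: a [surface_mesh()] (with a `scalars` attribute if
#'   present); `write_mesh()`: `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, scalars = NULL) {
  ext <- tolower(tools::file_ext(path))
  v <- mesh$vertices
  f <- mesh$faces
  if (ext == "ply") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property float x", "property float y", "property float z",
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices",
                 "end_header"), con)
    writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  } else if (ext == "vtk") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# vtk DataFile Version 3.0", "surfmorph mesh", "ASCII",
                 "DATASET POLYDATA",
                 sprintf("POINTS %d float", nrow(v))), con)
    writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("POLYGONS %d %d", nrow(f), 4 * nrow(f)), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
    if (!is.null(scalars)) {
      nm <- names(scalars)[1]
      vals <- scalars[[1]]
      writeLines(c(sprintf("POINT_DATA %d", nrow(v)),
                   sprintf("SCALARS %s float 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.9g", vals), con)
    }
  } else {
    abort(sprintf("unsupported mesh format '%s' (use .ply or .vtk)", ext))
  }
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path)
  if (ext == "ply") {
    hend <- match("end_header", lines)
    if (is.na(hend)) abort(sprintf("malformed PLY '%s': no end_header", path))
    nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)))
    nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)))
    vl <- lines[(hend + 1):(hend + nv)]
    fl <- lines[(hend + nv + 1):(hend + nv + nf)]
    v <- matrix(scan(text = vl, quiet = TRUE), ncol = 3, byrow = TRUE)
    f <- matrix(scan(text = fl, quiet = TRUE), ncol = 4, byrow = TRUE)[, 2:4] + 1L
    return(surface_mesh(v, f, clean = FALSE))
  }
  if (ext == "vtk") {
    pts_line <- grep("^POINTS", lines)
    nv <- as.integer(strsplit(lines[pts_line], " +")[[1]][2])
    coords <- scan(text = lines[(pts_line + 1):length(lines)], n = 3 * nv, quiet = TRUE)
    v <- matrix(coords, ncol = 3, byrow = TRUE)
    # POINTS may span a variable number of lines; locate POLYGONS
    pol_line <- grep("^POLYGONS", lines)
    npoly <- as.integer(strsplit(lines[pol_line], " +")[[1]][2])
    fvals <- scan(text = lines[(pol_line + 1):length(lines)], n = 4 * npoly, quiet = TRUE)
    f <- matrix(fvals, ncol = 4, byrow = TRUE)[, 2:4] + 1L
    mesh <- surface_mesh(v, f, clean = FALSE)
    sc_line <- grep("^SCALARS", lines)
    if (length(sc_line)) {
      nm <- strsplit(lines[sc_line[1]], " +")[[1]][2]
      vals <- scan(text = lines[(sc_line[1] + 2):length(lines)], n = nv, quiet = TRUE)
      attr(mesh, "scalars") <- setNames(list(vals), nm)
    }
    return(mesh)
  }
  abort(sprintf("unsupported mesh format '%s'", ext))
}

#' Read / write tabular data (CSV, strict missing-value policy)
#'
#' Complete-case analysis is the only missing-data policy in this pipeline,
#' so `read_table_strict()` refuses files with missing cells rather than
#' silently imputing, naming the offending rows and columns.
#'
#' @param tbl A data frame.
#' @param path CSV path with header row.
#' @param allow_missing Permit `NA` cells on read.
#' @return `read_table_strict()`: a [tibble::tibble()].
#' @export
write_table <- function(tbl, path) {
  utils::write.csv(tbl, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table_strict <- function(path, allow_missing = FALSE) {
  tbl <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if (!allow_missing && anyNA(tbl)) {
    bad <- which(!complete.cases(tbl))
    cols <- names(tbl)[vapply(tbl, anyNA, logical(1))]
    abort(sprintf(
      "missing values in '%s' (rows %s; columns %s); complete cases required",
      path, paste(head(bad, 5), collapse = ","), paste(cols, collapse = ",")))
  }
  tbl
}
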