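# File interchange: PLY meshes, NIfTI volumes, FSL bval/bvec text, and CSV
# vertex maps / cohort tables / subject-by-vertex matrices. Vertex indices
# are 1-based in memory and converted to 0-based on disk where the format
# expects it (PLY, vertex-map CSV).

#' Write a mesh as PLY
#'
#' @param mesh a [surface_mesh()].
#' @param path output file path.
#' @param format `"binary_little_endian"` (default) or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path, format = c("binary_little_endian", "ascii")) {
  format <- match.arg(format)
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  header <- c("ply",
              paste("format", format, "1.0"),
              paste("element vertex", nv),
              "property float x", "property float y", "property float z",
              paste("element face", nf),
              "property list uchar int vertex_indices",
              "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  if (format == "ascii") {
    writeLines(apply(mesh$vertices, 1L, paste, collapse = " "), con)
    writeLines(paste(3L, mesh$faces[, 1L] - 1L, mesh$faces[, 2L] - 1L,
                     mesh$faces[, 3L] - 1L), con)
  } else {
    writeBin(as.vector(t(mesh$vertices)), con, size = 4L, endian = "little")
    fl <- t(cbind(3L, mesh$faces - 1L))
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(fl[2:4, i]), con, size = 4L, endian = "little")
    }
  }
  invisible(path)
}

#' Read a PLY mesh
#'
#' Supports ascii and binary little-endian PLY with float vertex coordinates
#' and uchar-counted integer face lists, as written by [write_ply()].
#'
#' @param path PLY file path.
#' @return a [surface_mesh()].
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("truncated PLY header")
    header <- c(header, line)
    if (line == "end_header") break
  }
  fmt <- sub("^format ([a-z_]+) .*$", "\\1", grep("^format", header, value = TRUE))
  nv <- as.integer(sub("^element vertex ", "", grep("^element vertex", header, value = TRUE)))
  nf <- as.integer(sub("^element face ", "", grep("^element face", header, value = TRUE)))
  if (fmt == "ascii") {
    vl <- readLines(con, n = nv)
    verts <- matrix(as.numeric(unlist(strsplit(vl, " +"))), nv, byrow = TRUE)[, 1:3]
    flns <- readLines(con, n = nf)
    faces <- matrix(as.integer(unlist(strsplit(flns, " +"))), nf, byrow = TRUE)
    if (any(faces[, 1L] != 3L)) stop("only triangle faces are supported")
    faces <- faces[, 2:4, drop = FALSE] + 1L
  } else if (fmt == "binary_little_endian") {
    verts <- matrix(readBin(con, numeric(), n = nv * 3L, size = 4L,
                            endian = "little"), nv, 3L, byrow = TRUE)
    faces <- matrix(0L, nf, 3L)
    for (i in seq_len(nf)) {
      cnt <- as.integer(readBin(con, raw(), n = 1L))
      if (cnt != 3L) stop("only triangle faces are supported")
      faces[i, ] <- readBin(con, integer(), n = 3L, size = 4L,
                            endian = "little") + 1L
    }
  } else stop("unsupported PLY format: ", fmt)
  surface_mesh(verts, faces)
}

#' Write a scalar volume as NIfTI-1
#'
#' @param volume a [scalar_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(volume, path) {
  stopifnot(inherits(volume, "scalar_volume"))
  img <- RNifti::asNifti(volume$data)
  RNifti::sform(img) <- structure(volume$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 scalar volume
#'
#' @param path NIfTI file path.
#' @return a [scalar_volume()] (3-D) using the stored sform/qform affine.
#' @export
read_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  scalar_volume(array(as.numeric(img), dim(img)[1:3]), unclass(aff))
}

#' Write a DWI series as NIfTI-1 plus FSL bval/bvec files
#'
#' @param dwi a `dwi_volume`.
#' @param prefix path prefix; writes `<prefix>.nii.gz`, `<prefix>.bval`,
#'   `<prefix>.bvec`.
#' @return the three paths, invisibly.
#' @export
write_dwi <- function(dwi, prefix) {
  stopifnot(inherits(dwi, "dwi_volume"))
  img <- RNifti::asNifti(dwi$data)
  RNifti::sform(img) <- structure(dwi$affine, code = 2L)
  nii <- paste0(prefix, ".nii.gz")
  RNifti::writeNifti(img, nii)
  bval <- paste0(prefix, ".bval")
  bvec <- paste0(prefix, ".bvec")
  writeLines(paste(format(dwi$protocol$bvals, trim = TRUE), collapse = " "), bval)
  writeLines(apply(t(dwi$protocol$bvecs), 1L, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")), bvec)
  invisible(c(nii, bval, bvec))
}

#' Read a DWI series from NIfTI-1 plus FSL bval/bvec files
#'
#' @param prefix path prefix as in [write_dwi()] (or explicit paths).
#' @param nii,bval,bvec explicit file paths overriding the prefix.
#' @return a `dwi_volume`.
#' @export
read_dwi <- function(prefix, nii = NULL, bval = NULL, bvec = NULL) {
  if (is.null(nii)) nii <- paste0(prefix, ".nii.gz")
  if (is.null(bval)) bval <- paste0(prefix, ".bval")
  if (is.null(bvec)) bvec <- paste0(prefix, ".bvec")
  img <- RNifti::readNifti(nii)
  bvals <- scan(bval, quiet = TRUE)
  bvecs <- matrix(scan(bvec, quiet = TRUE), nrow = 3L, byrow = TRUE)
  protocol <- diffusion_protocol(bvals, bvecs)
  structure(list(data = array(as.numeric(img), dim(img)),
                 affine = unclass(RNifti::xform(img)),
                 protocol = protocol),
            class = "dwi_volume")
}

#' Write a per-vertex map as CSV
#'
#' Two columns: `vertex_id` (0-based on disk) and `value` (empty for
#' missing).
#'
#' @param values numeric vertex map.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_vertex_map <- function(values, path) {
  utils::write.csv(data.frame(vertex_id = seq_along(values) - 1L,
                              value = values),
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a per-vertex map CSV
#'
#' @param path file written by [write_vertex_map()].
#' @return numeric vector ordered by vertex id (`NA` for missing).
#' @export
read_vertex_map <- function(path) {
  df <- utils::read.csv(path)
  out <- rep(NA_real_, max(df$vertex_id) + 1L)
  out[df$vertex_id + 1L] <- df$value
  out
}

#' Write a subject-by-vertex matrix with its cohort sidecar
#'
#' @param Y subjects x vertices matrix (rows aligned with `cohort`).
#' @param cohort cohort data frame.
#' @param prefix path prefix; writes `<prefix>_maps.csv` and
#'   `<prefix>_cohort.csv`.
#' @return the two paths, invisibly.
#' @export
write_subject_matrix <- function(Y, cohort, prefix) {
  if (nrow(Y) != nrow(cohort)) stop("matrix rows do not match the cohort")
  maps <- file.path(paste0(prefix, "_maps.csv"))
  coh <- file.path(paste0(prefix, "_cohort.csv"))
  df <- as.data.frame(Y)
  names(df) <- paste0("v", seq_len(ncol(Y)) - 1L)
  utils::write.csv(cbind(id = cohort$id, df), maps, row.names = FALSE, na = "")
  utils::write.csv(cohort, coh, row.names = FALSE, na = "")
  invisible(c(maps, coh))
}

#' Read a subject-by-vertex matrix and its cohort sidecar
#'
#' @param prefix prefix used by [write_subject_matrix()].
#' @return list with `Y` (matrix) and `cohort` (data frame), row-aligned.
#' @export
read_subject_matrix <- function(prefix) {
  maps <- utils::read.csv(paste0(prefix, "_maps.csv"))
  cohort <- utils::read.csv(paste0(prefix, "_cohort.csv"))
  Y <- as.matrix(maps[, -1L, drop = FALSE])
  rownames(Y) <- maps$id
  if (!identical(as.character(maps$id), as.character(cohort$id)))
    stop("maps and cohort sidecar are not row-aligned")
  list(Y = Y, cohort = cohort)
}

#' Write a 4 x 4 affine as a row-major text file
#'
#' @param affine 4 x 4 matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_affine <- function(affine, path) {
  stopifnot(all(dim(affine) == c(4L, 4L)))
  writeLines(apply(affine, 1L, function(r)
    paste(format(r, digits = 17, trim = TRUE), collapse = " ")), path)
  invisible(path)
}

#' Read a 4 x 4 affine text file
#'
#' @param path file written by [write_affine()].
#' @return 4 x 4 numeric matrix.
#' @export
read_affine <- function(path) {
  matrix(scan(path, quiet = TRUE), 4L, 4L, byrow = TRUE)
}
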