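# Volumetric containers. Affines follow the NIfTI convention: world = A %*%
# c(i, j, k, 1) with zero-based voxel indices, RAS world coordinates in mm.

#' Scalar volume
#'
#' @param data 3-D numeric array (may contain `NA` for invalid voxels).
#' @param affine 4 x 4 voxel-to-world matrix (zero-based voxel indices).
#' @return object of class `scalar_volume`.
#' @export
scalar_volume <- function(data, affine) {
  stopifnot(length(dim(data)) == 3L, all(dim(affine) == c(4L, 4L)))
  structure(list(data = data, affine = affine), class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("scalar_volume: %s grid, %d invalid voxels\n",
              paste(dim(x$data), collapse = " x "), sum(is.na(x$data))))
  invisible(x)
}

#' Diffusion tensor volume
#'
#' Per-voxel symmetric tensor stored as its 6 unique elements in the order
#' `xx, yy, zz, xy, xz, yz` (mm^2/s), together with `log(S0)` and a validity
#' mask.
#'
#' @param D 4-D array `dim = c(nx, ny, nz, 6)`.
#' @param log_s0 3-D array of log non-diffusion-weighted signal.
#' @param affine 4 x 4 voxel-to-world matrix.
#' @param valid logical 3-D array marking voxels with a usable tensor.
#' @param qc optional list of QC flag arrays (e.g. clamped signals,
#'   non-positive-definite fits).
#' @return object of class `tensor_volume`.
#' @export
tensor_volume <- function(D, log_s0, affine, valid = NULL, qc = list()) {
  stopifnot(length(dim(D)) == 4L, dim(D)[4L] == 6L)
  if (is.null(valid)) valid <- array(TRUE, dim(D)[1:3])
  structure(list(D = D, log_s0 = log_s0, affine = affine, valid = valid, qc = qc),
            class = "tensor_volume")
}

#' @export
print.tensor_volume <- function(x, ...) {
  cat(sprintf("tensor_volume: %s grid, %d valid voxels\n",
              paste(dim(x$D)[1:3], collapse = " x "), sum(x$valid)))
  invisible(x)
}

# Centered scaled-identity affine for an isotropic grid of `dims` voxels of
# size `voxel` mm, grid centered on the world origin.
centered_affine <- function(dims, voxel) {
  a <- diag(c(voxel, voxel, voxel, 1))
  a[1:3, 4L] <- -voxel * (dims - 1) / 2
  a
}

# World coordinates of every voxel center, as an (nvox x 3) matrix ordered
# like `as.vector(array)` (x fastest).
voxel_centers <- function(dims, affine) {
  ijk <- cbind(
    rep.int(seq_len(dims[1L]) - 1L, dims[2L] * dims[3L]),
    rep.int(rep(seq_len(dims[2L]) - 1L, each = dims[1L]), dims[3L]),
    rep(seq_len(dims[3L]) - 1L, each = dims[1L] * dims[2L]))
  sweep(ijk %*% t(affine[1:3, 1:3]), 2L, affine[1:3, 4L], "+")
}
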