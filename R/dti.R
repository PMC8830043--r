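# Log-linear (OLS) diffusion tensor fit and mean diffusivity, mirroring the
# default behaviour of FSL's dtifit.

#' Fit diffusion tensors by ordinary least squares on log signals
#'
#' Per voxel, solves `ln S(g, b) = ln S0 - b * g' D g` by OLS with design
#' columns `[1, -b gx^2, -b gy^2, -b gz^2, -2b gx gy, -2b gx gz, -2b gy gz]`.
#' The log model is exact on noiseless single-tensor data, so noiseless
#' round trips recover the tensor to machine precision.
#'
#' Non-positive signals (possible under Rician noise at high attenuation) are
#' clamped to `1e-6 * S0` (per-voxel mean b = 0 signal) before taking logs and
#' the voxel is flagged in `qc$clamped`. Fitted tensors that are not positive
#' definite are flagged in `qc$not_positive_definite`; their trace is still
#' used for MD (no eigenvalue clipping).
#'
#' @param dwi a `dwi_volume` (or 4-D array with an `affine` attribute
#'   supplied via `affine`).
#' @param protocol a [diffusion_protocol()]; defaults to the protocol stored
#'   in `dwi`.
#' @param mask optional logical 3-D array restricting the fit; voxels outside
#'   are invalid in the output.
#' @param affine affine override when `dwi` is a bare array.
#' @return a [tensor_volume()] with QC flags.
#' @export
fit_tensor_loglinear <- function(dwi, protocol = NULL, mask = NULL, affine = NULL) {
  if (inherits(dwi, "dwi_volume")) {
    if (is.null(protocol)) protocol <- dwi$protocol
    affine <- dwi$affine
    data <- dwi$data
  } else {
    data <- dwi
    if (is.null(affine)) affine <- diag(4)
  }
  stopifnot(inherits(protocol, "diffusion_protocol"), length(dim(data)) == 4L)
  dims <- dim(data)[1:3]
  nvol <- dim(data)[4L]
  if (nvol != length(protocol$bvals))
    stop("number of volumes does not match protocol length")
  if (is.null(mask)) mask <- array(TRUE, dims)

  X <- tensor_design(protocol$bvals, protocol$bvecs)
  qx <- qr(X)
  if (qx$rank < 7L)
    stop("protocol defect: tensor design matrix is rank-deficient ",
         "(collinear or insufficient diffusion directions)")

  idx <- which(as.vector(mask))
  S <- matrix(data, prod(dims), nvol)[idx, , drop = FALSE]
  b0 <- protocol$bvals == 0
  s0_est <- rowMeans(S[, b0, drop = FALSE])
  bad_s0 <- !is.finite(s0_est) | s0_est <= 0
  clamped <- rowSums(S <= 0) > 0 | bad_s0
  eps <- pmax(1e-6 * s0_est, .Machine$double.xmin)
  eps[bad_s0] <- .Machine$double.xmin
  S <- pmax(S, eps)  # recycles eps down columns
  coef <- qr.coef(qx, t(log(S)))  # 7 x nvox_masked

  Dfull <- matrix(0, prod(dims), 6L)
  Dfull[idx, ] <- t(coef[-1L, , drop = FALSE])
  log_s0 <- rep(NA_real_, prod(dims))
  log_s0[idx] <- coef[1L, ]
  valid <- rep(FALSE, prod(dims))
  valid[idx] <- !bad_s0

  # Sylvester criterion for positive definiteness (vectorized)
  dxx <- Dfull[, 1L]; dyy <- Dfull[, 2L]; dzz <- Dfull[, 3L]
  dxy <- Dfull[, 4L]; dxz <- Dfull[, 5L]; dyz <- Dfull[, 6L]
  m2 <- dxx * dyy - dxy^2
  m3 <- dxx * (dyy * dzz - dyz^2) - dxy * (dxy * dzz - dyz * dxz) +
    dxz * (dxy * dyz - dyy * dxz)
  npd <- valid & !(dxx > 0 & m2 > 0 & m3 > 0)

  clamp_flag <- rep(FALSE, prod(dims))
  clamp_flag[idx] <- clamped
  tensor_volume(D = array(Dfull, c(dims, 6L)),
                log_s0 = array(log_s0, dims),
                affine = affine,
                valid = array(valid, dims),
                qc = list(clamped = array(clamp_flag, dims),
                          not_positive_definite = array(npd, dims)))
}

#' Mean diffusivity map
#'
#' MD = trace(D) / 3 = (Dxx + Dyy + Dzz) / 3 per voxel; invalid voxels
#' propagate as `NA`.
#'
#' @param tensors a [tensor_volume()].
#' @return a [scalar_volume()] of MD in mm^2/s.
#' @export
mean_diffusivity <- function(tensors) {
  stopifnot(inherits(tensors, "tensor_volume"))
  dims <- dim(tensors$D)[1:3]
  md <- (as.vector(tensors$D[, , , 1L]) +
         as.vector(tensors$D[, , , 2L]) +
         as.vector(tensors$D[, , , 3L])) / 3
  md[!as.vector(tensors$valid)] <- NA_real_
  scalar_volume(array(md, dims), tensors$affine)
}
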