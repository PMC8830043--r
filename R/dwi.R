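# Diffusion protocol and forward DWI synthesis from a tensor field.

#' Diffusion acquisition protocol
#'
#' @param bvals numeric vector of b-values, s/mm^2.
#' @param bvecs 3 x n or n x 3 matrix of gradient directions; directions at
#'   b > 0 must be unit vectors (within 1e-4). Vectors at b = 0 are ignored.
#' @return object of class `diffusion_protocol` with `bvals` and an n x 3
#'   `bvecs` matrix.
#' @export
diffusion_protocol <- function(bvals, bvecs) {
  bvecs <- as.matrix(bvecs)
  if (ncol(bvecs) != 3L && nrow(bvecs) == 3L) bvecs <- t(bvecs)
  if (ncol(bvecs) != 3L) stop("bvecs must be n x 3 (or 3 x n)")
  if (length(bvals) != nrow(bvecs))
    stop("bvals and bvecs lengths differ")
  dw <- bvals > 0
  if (!any(!dw)) stop("protocol must contain at least one b = 0 volume")
  nrm <- sqrt(rowSums(bvecs[dw, , drop = FALSE]^2))
  if (any(abs(nrm - 1) > 1e-4))
    stop("b > 0 gradient directions must have unit norm (within 1e-4)")
  if (sum(dw) < 6L)
    stop("protocol defect: fewer than 6 diffusion-weighted directions")
  # non-collinearity: the quadratic-form design must have rank 6
  X <- tensor_design(bvals[dw], bvecs[dw, , drop = FALSE])[, -1L, drop = FALSE]
  if (qr(X)$rank < 6L)
    stop("protocol defect: diffusion directions are collinear (tensor design rank-deficient)")
  structure(list(bvals = as.numeric(bvals), bvecs = bvecs),
            class = "diffusion_protocol")
}

#' @export
print.diffusion_protocol <- function(x, ...) {
  cat(sprintf("diffusion_protocol: %d volumes (%d b=0, b max %g s/mm^2)\n",
              length(x$bvals), sum(x$bvals == 0), max(x$bvals)))
  invisible(x)
}

#' Deterministic near-uniform gradient scheme
#'
#' Fibonacci-spiral directions on the hemisphere plus `n_b0` leading b = 0
#' volumes; a convenient default protocol for simulations.
#'
#' @param n_directions number of diffusion-weighted directions (>= 6).
#' @param bval b-value of the weighted volumes, s/mm^2.
#' @param n_b0 number of b = 0 volumes.
#' @return a [diffusion_protocol()].
#' @export
default_protocol <- function(n_directions = 30L, bval = 1000, n_b0 = 1L) {
  stopifnot(n_directions >= 6L, n_b0 >= 1L, bval > 0)
  i <- seq_len(n_directions) - 0.5
  z <- i / n_directions              # hemisphere, avoids antipodal duplicates
  phi <- pi * (1 + sqrt(5)) * i
  s <- sqrt(1 - z^2)
  dirs <- cbind(s * cos(phi), s * sin(phi), z)
  diffusion_protocol(c(rep(0, n_b0), rep(bval, n_directions)),
                     rbind(matrix(0, n_b0, 3L), dirs))
}

# Design matrix of the log-linear tensor model: columns
# [1, -b gx^2, -b gy^2, -b gz^2, -2b gx gy, -2b gx gz, -2b gy gz],
# matching the tensor element order (xx, yy, zz, xy, xz, yz).
tensor_design <- function(bvals, bvecs) {
  g <- bvecs
  b <- bvals
  cbind(1,
        -b * g[, 1L]^2, -b * g[, 2L]^2, -b * g[, 3L]^2,
        -2 * b * g[, 1L] * g[, 2L],
        -2 * b * g[, 1L] * g[, 3L],
        -2 * b * g[, 2L] * g[, 3L])
}

# Evaluate RNG-consuming code under a seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthesize diffusion-weighted volumes from a tensor field
#'
#' Noiseless signal follows the single-tensor model
#' `S(g, b) = S0 * exp(-b * g' D g)` per voxel. Rician noise of scale
#' `noise_sigma` is added as independent Gaussian noise on the in-phase and
#' quadrature channels followed by magnitude formation. Invalid voxels (zero
#' tensor, no S0) produce zero signal plus noise.
#'
#' @param tensors a [tensor_volume()].
#' @param protocol a [diffusion_protocol()].
#' @param noise_sigma Rician noise scale (signal units); 0 for noiseless data.
#' @param seed integer seed making the noise reproducible; `NULL` uses the
#'   current RNG state.
#' @return object of class `dwi_volume`: 4-D `data` array
#'   (`nx, ny, nz, n_volumes`), `affine`, and the protocol.
#' @export
simulate_dwi <- function(tensors, protocol, noise_sigma = 0, seed = NULL) {
  stopifnot(inherits(tensors, "tensor_volume"),
            inherits(protocol, "diffusion_protocol"),
            noise_sigma >= 0)
  dims <- dim(tensors$D)[1:3]
  nvox <- prod(dims)
  Dm <- matrix(tensors$D, nvox, 6L)
  s0 <- exp(as.vector(tensors$log_s0))
  s0[!as.vector(tensors$valid)] <- 0
  nvol <- length(protocol$bvals)
  X <- tensor_design(protocol$bvals, protocol$bvecs)[, -1L, drop = FALSE]
  # log attenuation per voxel/volume: nvox x nvol
  S <- s0 * exp(Dm %*% t(X))
  if (noise_sigma > 0) {
    S <- with_seed(seed, {
      n1 <- matrix(stats::rnorm(nvox * nvol, sd = noise_sigma), nvox, nvol)
      n2 <- matrix(stats::rnorm(nvox * nvol, sd = noise_sigma), nvox, nvol)
      sqrt((S + n1)^2 + n2^2)
    })
  }
  structure(list(data = array(S, c(dims, nvol)),
                 affine = tensors$affine,
                 protocol = protocol),
            class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  cat(sprintf("dwi_volume: %s grid, %d volumes\n",
              paste(dim(x$data)[1:3], collapse = " x "), dim(x$data)[4L]))
  invisible(x)
}
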