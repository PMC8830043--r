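# Tensor fitting: exactness on noiseless data, oracle agreement, rotation
# invariance of MD, and noise robustness.

make_iso_dwi <- function(md, protocol, s0 = 1000) {
  dims <- c(2L, 2L, 2L)
  D <- array(0, c(dims, 6L))
  D[, , , 1:3] <- md
  tv <- tensor_volume(D, array(log(s0), dims), centered_affine(dims, 1))
  simulate_dwi(tv, protocol)
}
centered_affine <- cortexmd:::centered_affine

test_that("noiseless isotropic signal follows S0 * exp(-b * MD) exactly", {
  prot <- default_protocol(12, 1000)
  dwi <- make_iso_dwi(0.8e-3, prot)
  dwv <- prot$bvals > 0
  # 1000 * exp(-0.8) = 449.3290 for every direction
  expect_equal(unique(round(as.vector(dwi$data[, , , dwv]), 6)),
               round(1000 * exp(-0.8), 6))
  # b = 0 returns S0 (zero attenuation; only exp/log representation error)
  expect_equal(as.vector(dwi$data[, , , !dwv]), rep(1000, 8), tolerance = 1e-12)
})

test_that("log-linear fit recovers noiseless tensors to machine precision", {
  prot <- default_protocol(12, 1000)
  dwi <- make_iso_dwi(0.8e-3, prot)
  fit <- fit_tensor_loglinear(dwi)
  md <- mean_diffusivity(fit)
  expect_lt(max(abs(md$data - 0.8e-3)), 1e-13)

  # anisotropic diag(1.7, 0.3, 0.3)e-3 with 30 directions: all 6 elements
  prot30 <- default_protocol(30, 1000)
  dims <- c(2L, 2L, 2L)
  D <- array(0, c(dims, 6L))
  D[, , , 1L] <- 1.7e-3; D[, , , 2L] <- 0.3e-3; D[, , , 3L] <- 0.3e-3
  tv <- tensor_volume(D, array(log(1000), dims), centered_affine(dims, 1))
  dwi2 <- simulate_dwi(tv, prot30)
  fit2 <- fit_tensor_loglinear(dwi2)
  expect_lt(max(abs(fit2$D - D)) / 1.7e-3, 1e-10)

  # independent pseudo-inverse oracle for one voxel
  X <- cortexmd:::tensor_design(prot30$bvals, prot30$bvecs)
  y <- log(as.vector(dwi2$data[1, 1, 1, ]))
  coef_oracle <- solve(t(X) %*% X) %*% t(X) %*% y
  expect_equal(as.vector(fit2$D[1, 1, 1, ]), as.vector(coef_oracle[-1L]),
               tolerance = 1e-10)
  expect_equal(fit2$log_s0[1, 1, 1], coef_oracle[1L], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("MD is invariant under rotation of the gradient frame", {
  set.seed(71)
  prot <- default_protocol(24, 1000)
  dims <- c(1L, 1L, 1L)
  # random positive-definite tensor
  A <- matrix(rnorm(9, sd = 1e-3), 3)
  Dm <- crossprod(A) / 3 + diag(3) * 2e-4
  for (rep in 1:5) {
    Q <- qr.Q(qr(matrix(rnorm(9), 3)))
    Dr <- Q %*% Dm %*% t(Q)
    D <- array(c(Dr[1, 1], Dr[2, 2], Dr[3, 3], Dr[1, 2], Dr[1, 3], Dr[2, 3]),
               c(dims, 6L))
    tv <- tensor_volume(D, array(log(500), dims), centered_affine(dims, 1))
    fit <- fit_tensor_loglinear(simulate_dwi(tv, prot))
    expect_equal(mean_diffusivity(fit)$data[1, 1, 1],
                 sum(diag(Dm)) / 3, tolerance = 1e-10)
  }
})

test_that("protocol validation rejects degenerate acquisitions", {
  expect_error(diffusion_protocol(c(0, 0, 0), matrix(0, 3, 3)),
               "fewer than 6")
  expect_error(diffusion_protocol(rep(1000, 7), matrix(rep(c(1, 0, 0), 7), 7, 3,
                                                       byrow = TRUE)),
               "at least one b = 0")
  # 6+ repeats of the same direction: collinear
  bv <- rbind(c(0, 0, 0), matrix(rep(c(1, 0, 0), 7), 7, 3, byrow = TRUE))
  expect_error(diffusion_protocol(c(0, rep(1000, 7)), bv), "collinear")
  # non-unit vectors
  expect_error(diffusion_protocol(c(0, rep(1000, 6)),
                                  rbind(c(0, 0, 0), default_protocol(6)$bvecs[-1, ] * 2)),
               "unit norm")
})

test_that("non-positive signals are clamped and flagged, not fatal", {
  prot <- default_protocol(8, 1000)
  dims <- c(1L, 1L, 1L)
  data <- array(rep(100, length(prot$bvals)), c(dims, length(prot$bvals)))
  data[1, 1, 1, 5] <- -3
  fit <- fit_tensor_loglinear(data, prot)
  expect_true(fit$qc$clamped[1, 1, 1])
  expect_true(fit$valid[1, 1, 1])
})

test_that("median MD bias under Rician noise is below 2% (b=1000, 30 dirs)", {
  prot <- default_protocol(30, 1000)
  dims <- c(12L, 12L, 12L)
  D <- array(0, c(dims, 6L))
  D[, , , 1:3] <- 0.8e-3
  tv <- tensor_volume(D, array(log(1000), dims), centered_affine(dims, 1))
  dwi <- simulate_dwi(tv, prot, noise_sigma = 20, seed = 99)  # sigma = 2% of S0
  md <- mean_diffusivity(fit_tensor_loglinear(dwi))
  expect_lt(abs(median(md$data) - 0.8e-3) / 0.8e-3, 0.02)
})

test_that("DWI synthesis is deterministic given the seed", {
  prot <- default_protocol(12, 1000)
  dims <- c(3L, 3L, 3L)
  D <- array(0, c(dims, 6L)); D[, , , 1:3] <- 1e-3
  tv <- tensor_volume(D, array(log(800), dims), centered_affine(dims, 1))
  a <- simulate_dwi(tv, prot, noise_sigma = 30, seed = 4)
  b <- simulate_dwi(tv, prot, noise_sigma = 30, seed = 4)
  cc <- simulate_dwi(tv, prot, noise_sigma = 30, seed = 5)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, cc$data))
})
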