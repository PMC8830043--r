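# Ribbon midpoints, volume sampling, thickness, and geodesic smoothing.

test_that("ribbon midpoints are the per-vertex white/pial midpoints", {
  w <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(c(1L, 2L, 3L)))
  p <- surface_mesh(rbind(c(0, 0, 2), c(1, 0, 2), c(0, 1, 2)), rbind(c(1L, 2L, 3L)))
  pair <- surface_pair(w, p)
  expect_equal(ribbon_midpoints(pair), w$vertices + matrix(c(0, 0, 1), 3, 3, byrow = TRUE))
  expect_equal(cortical_thickness(pair), rep(2, 3))
  # identical surfaces: midpoint = surface, thickness = 0
  same <- surface_pair(w, w)
  expect_equal(ribbon_midpoints(same), w$vertices)
  expect_equal(cortical_thickness(same), rep(0, 3))
  # mismatched pairs are rejected
  w2 <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)),
                     rbind(c(1L, 2L, 3L), c(2L, 4L, 3L)))
  expect_error(surface_pair(w2, p), "vertex counts")
})

test_that("sphere phantom: midpoints at r 51.5 and thickness 3.0 everywhere", {
  spec <- phantom_spec(icosphere_subdivisions = 2, baseline_thickness = 3)
  pair <- make_surface_pair(spec)
  mid <- ribbon_midpoints(pair)
  expect_lt(max(abs(sqrt(rowSums(mid^2)) - 51.5)), 1e-9)
  expect_lt(max(abs(cortical_thickness(pair) - 3)), 1e-9)
})

test_that("trilinear sampling is exact for constant and affine fields", {
  dims <- c(8L, 9L, 10L)
  aff <- cortexmd:::centered_affine(dims, 2)
  ctr <- cortexmd:::voxel_centers(dims, aff)
  set.seed(5)
  pts <- matrix(runif(60, -5, 5), 20, 3)

  vol_c <- scalar_volume(array(3.14, dims), aff)
  expect_equal(sample_volume_at_points(vol_c, pts), rep(3.14, 20))

  vol_x <- scalar_volume(array(ctr[, 1], dims), aff)
  expect_lt(max(abs(sample_volume_at_points(vol_x, pts) - pts[, 1])), 1e-9)

  # outside the field of view: missing, never extrapolated
  out <- sample_volume_at_points(vol_x, rbind(c(100, 0, 0), c(0, 0, 0)))
  expect_true(is.na(out[1]))
  expect_false(is.na(out[2]))

  # touching an invalid voxel: missing
  d <- array(1, dims)
  d[4, 5, 5] <- NA
  vol_na <- scalar_volume(d, aff)
  near <- ctr[which(is.na(as.vector(d))), , drop = FALSE] + 0.5
  expect_true(is.na(sample_volume_at_points(vol_na, near)))

  expect_error(sample_volume_at_points(vol_x, rbind(c(Inf, 0, 0))), "finite")
  expect_error(sample_volume_at_points(vol_x, pts, affine_adjust = matrix(0, 4, 4)),
               "singular")
})

test_that("an affine_adjust maps surface coordinates into the volume frame", {
  dims <- c(10L, 10L, 10L)
  aff <- cortexmd:::centered_affine(dims, 2)
  ctr <- cortexmd:::voxel_centers(dims, aff)
  vol <- scalar_volume(array(ctr[, 2], dims), aff)  # field = world y
  shift <- diag(4); shift[2, 4] <- 3                # surface frame offset by +3 in y
  pts <- matrix(c(0, 0, 0, 1, -2, 1), 2, 3, byrow = TRUE)
  got <- sample_volume_at_points(vol, pts, affine_adjust = shift)
  expect_equal(got, pts[, 2] + 3, tolerance = 1e-9)
})

test_that("smoothing: identity cases, constant invariance, error cases", {
  m <- ico3()
  x <- rnorm(nrow(m$vertices))
  expect_identical(smooth_vertex_map(m, x, 0), x)
  sm <- smooth_vertex_map(m, rep(2.5, nrow(m$vertices)), 15,
                          kernel = ico3_kernel15())
  expect_lt(max(abs(sm - 2.5)), 1e-12)
  expect_error(smooth_vertex_map(m, x, -1), "non-negative")
  expect_error(smooth_vertex_map(m, x[-1], 15), "length")
})

test_that("missing vertices are excluded from smoothing and stay missing", {
  m <- ico3()
  K <- ico3_kernel15()
  x <- rep(1, nrow(m$vertices))
  x[10:20] <- NA
  sm <- smooth_vertex_map(m, x, 15, kernel = K)
  expect_true(all(is.na(sm[10:20])))
  expect_lt(max(abs(sm[-(10:20)] - 1)), 1e-12)  # renormalized over non-missing
})

test_that("smoothing preserves the area-weighted mean of complete maps", {
  m <- ico3()
  ar <- ico3_areas()
  set.seed(8)
  x <- rnorm(nrow(m$vertices))
  sm <- smooth_vertex_map(m, x, 15, kernel = ico3_kernel15())
  m0 <- sum(ar * x) / sum(ar)
  m1 <- sum(ar * sm) / sum(ar)
  expect_lt(abs(m1 - m0), 0.01 * sd(x))
})

test_that("impulse response width matches the requested 15 mm FWHM", {
  m <- icosphere(4, 50)
  g <- mesh_graph(m)
  K <- smoothing_kernel(m, 15, g)
  imp <- rep(0, nrow(m$vertices)); imp[1] <- 1
  sm <- smooth_vertex_map(m, imp, 15, kernel = K)
  d <- as.vector(igraph::distances(g, v = 1))
  ord <- order(d)
  half <- max(sm) / 2
  i <- which(sm[ord] < half)[1]
  r_half <- approx(sm[ord][c(i - 1, i)], d[ord][c(i - 1, i)], xout = half)$y
  expect_lt(abs(2 * r_half - 15) / 15, 0.15)
})

test_that("operations are invariant under a consistent rigid transform", {
  spec <- phantom_spec(icosphere_subdivisions = 2, baseline_thickness = 3)
  pair <- make_surface_pair(spec)
  tv <- make_tensor_volume(spec, pair)
  md <- mean_diffusivity(tv)
  mid <- ribbon_midpoints(pair)
  s0 <- sample_volume_at_points(md, mid)

  set.seed(3)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  t3 <- c(5, -7, 2)
  R4 <- rbind(cbind(Q, t3), c(0, 0, 0, 1))
  rot <- function(v) sweep(v %*% t(Q), 2, t3, "+")
  pair_r <- surface_pair(surface_mesh(rot(pair$white$vertices), pair$white$faces),
                         surface_mesh(rot(pair$pial$vertices), pair$pial$faces))
  md_r <- scalar_volume(md$data, R4 %*% md$affine)
  s1 <- sample_volume_at_points(md_r, ribbon_midpoints(pair_r))
  expect_equal(s1, s0, tolerance = 1e-6)
  expect_equal(cortical_thickness(pair_r), cortical_thickness(pair), tolerance = 1e-9)
  expect_equal(vertex_areas(pair_r$white), vertex_areas(pair$white), tolerance = 1e-9)
})
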