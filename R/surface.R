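# Cortical-ribbon operations: midpoint sampling, thickness, and geodesic
# Gaussian smoothing of vertex maps.

#' Midpoints of the cortical ribbon
#'
#' For each corresponding vertex pair, the point half way between the white
#' and pial surfaces: `m_v = w_v + 0.5 * (p_v - w_v)`. MD is sampled here to
#' minimize partial-volume contamination from white matter and CSF.
#'
#' @param pair a [surface_pair()].
#' @return N x 3 matrix of world coordinates (mm).
#' @export
ribbon_midpoints <- function(pair) {
  stopifnot(inherits(pair, "surface_pair"))
  (pair$white$vertices + pair$pial$vertices) / 2
}

#' Per-vertex cortical thickness
#'
#' Euclidean distance between corresponding white and pial vertices, mm.
#'
#' @param pair a [surface_pair()].
#' @return numeric vector of thickness values.
#' @export
cortical_thickness <- function(pair) {
  stopifnot(inherits(pair, "surface_pair"))
  sqrt(rowSums((pair$pial$vertices - pair$white$vertices)^2))
}

#' Sample a scalar volume at world-space points
#'
#' Points are mapped to (zero-based, continuous) voxel coordinates through the
#' volume affine, optionally composed with an extra alignment affine, and the
#' volume is interpolated trilinearly among the 8 surrounding voxel centers.
#' Points outside the grid, or whose interpolation neighborhood touches an
#' invalid (`NA`) voxel, return `NA` — values are never extrapolated.
#'
#' @param volume a [scalar_volume()].
#' @param points N x 3 matrix of world coordinates (mm).
#' @param affine_adjust optional 4 x 4 affine mapping point (surface) world
#'   coordinates into the volume's world frame (e.g. a diffusion-to-anatomical
#'   registration); identity by default.
#' @return numeric vector of sampled values with `NA` for unsampled points.
#' @export
sample_volume_at_points <- function(volume, points, affine_adjust = NULL) {
  stopifnot(inherits(volume, "scalar_volume"))
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must be N x 3")
  if (any(!is.finite(points))) stop("points must be finite")
  A <- volume$affine
  if (!is.null(affine_adjust)) {
    if (abs(det(affine_adjust)) < .Machine$double.eps)
      stop("affine_adjust is singular")
    points <- sweep(points %*% t(affine_adjust[1:3, 1:3]), 2L,
                    affine_adjust[1:3, 4L], "+")
  }
  if (abs(det(A)) < .Machine$double.eps) stop("volume affine is singular")
  Ainv <- solve(A)
  vox <- sweep(points %*% t(Ainv[1:3, 1:3]), 2L, Ainv[1:3, 4L], "+")

  dims <- dim(volume$data)
  i0 <- floor(vox)
  fr <- vox - i0
  ok <- i0[, 1L] >= 0 & i0[, 1L] <= dims[1L] - 2 &
        i0[, 2L] >= 0 & i0[, 2L] <= dims[2L] - 2 &
        i0[, 3L] >= 0 & i0[, 3L] <= dims[3L] - 2
  out <- rep(NA_real_, nrow(points))
  if (!any(ok)) return(out)
  i0 <- i0[ok, , drop = FALSE]
  fr <- fr[ok, , drop = FALSE]
  vol <- volume$data
  val <- numeric(sum(ok))
  nalist <- rep(FALSE, sum(ok))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dx) fr[, 1L] else 1 - fr[, 1L]) *
         (if (dy) fr[, 2L] else 1 - fr[, 2L]) *
         (if (dz) fr[, 3L] else 1 - fr[, 3L])
    lin <- (i0[, 1L] + dx) + dims[1L] * ((i0[, 2L] + dy) +
           dims[2L] * (i0[, 3L] + dz)) + 1
    v <- vol[lin]
    nalist <- nalist | is.na(v)
    v[is.na(v)] <- 0
    val <- val + w * v
  }
  val[nalist] <- NA_real_
  out[ok] <- val
  out
}

#' Geodesic Gaussian smoothing kernel of a mesh
#'
#' Sparse kernel matrix `K` with `K[u, v] = exp(-d(u, v)^2 / (2 sigma^2))`
#' where `d` is the geodesic (shortest weighted edge-path) distance, truncated
#' at `3 sigma`; `sigma = fwhm / sqrt(8 log 2)`. Rows are *not* normalized —
#' [smooth_vertex_map()] renormalizes over non-missing vertices so missing
#' data never bias the average.
#'
#' Precompute the kernel once when smoothing many maps on the same mesh.
#'
#' @param mesh a [surface_mesh()].
#' @param fwhm full width at half maximum of the kernel, mm.
#' @param graph optional precomputed [mesh_graph()].
#' @return a sparse symmetric `Matrix::dgCMatrix`.
#' @export
smoothing_kernel <- function(mesh, fwhm, graph = NULL) {
  stopifnot(fwhm > 0)
  sigma <- fwhm / sqrt(8 * log(2))
  if (is.null(graph)) graph <- mesh_graph(mesh)
  d <- igraph::distances(graph, algorithm = "dijkstra")
  keep <- d <= 3 * sigma
  w <- exp(-d[keep]^2 / (2 * sigma^2))
  ij <- which(keep, arr.ind = TRUE)
  Matrix::sparseMatrix(i = ij[, 1L], j = ij[, 2L], x = w,
                       dims = dim(d))
}

#' Smooth a vertex map with a geodesic Gaussian kernel
#'
#' Weighted average over vertices within 3 sigma geodesic distance, with
#' Gaussian weights renormalized to sum to one over the non-missing
#' neighbors. `fwhm = 0` is the identity. Vertices that are missing in the
#' input stay missing in the output.
#'
#' @param mesh a [surface_mesh()].
#' @param values numeric per-vertex map (`NA` = missing).
#' @param fwhm kernel FWHM in mm (the pipeline default is 15 mm).
#' @param kernel optional precomputed [smoothing_kernel()].
#' @param graph optional precomputed [mesh_graph()].
#' @return smoothed numeric vector.
#' @export
smooth_vertex_map <- function(mesh, values, fwhm = 15, kernel = NULL, graph = NULL) {
  if (fwhm < 0) stop("fwhm must be non-negative")
  nv <- nrow(mesh$vertices)
  if (length(values) != nv) stop("map length does not match vertex count")
  if (fwhm == 0) return(as.numeric(values))
  if (is.null(kernel)) kernel <- smoothing_kernel(mesh, fwhm, graph)
  miss <- is.na(values)
  x <- values
  x[miss] <- 0
  num <- as.vector(kernel %*% x)
  den <- as.vector(kernel %*% as.numeric(!miss))
  out <- num / den
  out[den == 0 | miss] <- NA_real_
  out
}

#' Smooth the rows of a subjects x vertices matrix
#'
#' Applies [smooth_vertex_map()] to every row with a shared precomputed
#' kernel; missing entries are excluded per row exactly as in the
#' single-map case.
#'
#' @param mesh a [surface_mesh()].
#' @param Y subjects x vertices matrix.
#' @param fwhm kernel FWHM in mm.
#' @param kernel,graph optional precomputed mesh quantities.
#' @return smoothed matrix of the same shape.
#' @export
smooth_matrix <- function(mesh, Y, fwhm = 15, kernel = NULL, graph = NULL) {
  if (fwhm == 0) return(Y)
  if (is.null(kernel)) kernel <- smoothing_kernel(mesh, fwhm, graph)
  miss <- is.na(Y)
  if (!any(miss)) {
    out <- as.matrix(Matrix::tcrossprod(Y, kernel))
  } else {
    X <- Y
    X[miss] <- 0
    num <- as.matrix(Matrix::tcrossprod(X, kernel))
    den <- as.matrix(Matrix::tcrossprod((!miss) * 1, kernel))
    out <- num / den
    out[den == 0 | miss] <- NA_real_
  }
  dimnames(out) <- dimnames(Y)
  out
}
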