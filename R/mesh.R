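# Triangle-mesh container and geometry used throughout the surface pipeline.
# Vertices are N x 3 world coordinates in mm; faces are M x 3 one-based vertex
# indices with counter-clockwise outward orientation.

#' Construct a triangle surface mesh
#'
#' @param vertices numeric N x 3 matrix of vertex coordinates (mm).
#' @param faces integer M x 3 matrix of 1-based vertex indices, counter-clockwise
#'   when seen from outside.
#' @param check if `TRUE`, validate index ranges and reject degenerate
#'   (zero-area) faces.
#' @return an object of class `surface_mesh` with elements `vertices` and
#'   `faces`.
#' @export
surface_mesh <- function(vertices, faces, check = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an N x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an M x 3 matrix")
  if (check) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face indices out of range")
    a <- triangle_areas(vertices, faces)
    if (any(a <= 0))
      stop("mesh contains degenerate (zero-area) faces")
  }
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces, total area %.1f mm^2\n",
              nrow(x$vertices), nrow(x$faces), sum(triangle_areas(x$vertices, x$faces))))
  invisible(x)
}

#' Pair of corresponding white and pial surfaces
#'
#' The two meshes must share the face list and have 1:1 vertex correspondence;
#' the space between them is the cortical ribbon.
#'
#' @param white,pial `surface_mesh` objects with identical topology.
#' @return an object of class `surface_pair`.
#' @export
surface_pair <- function(white, pial) {
  stopifnot(inherits(white, "surface_mesh"), inherits(pial, "surface_mesh"))
  if (nrow(white$vertices) != nrow(pial$vertices))
    stop("white and pial surfaces have different vertex counts")
  if (!identical(white$faces, pial$faces))
    stop("white and pial surfaces have different face lists")
  structure(list(white = white, pial = pial), class = "surface_pair")
}

#' @export
print.surface_pair <- function(x, ...) {
  th <- cortical_thickness(x)
  cat(sprintf("surface_pair: %d vertices, thickness %.2f-%.2f mm (mean %.2f)\n",
              nrow(x$white$vertices), min(th), max(th), mean(th)))
  invisible(x)
}

triangle_areas <- function(vertices, faces) {
  e1 <- vertices[faces[, 2L], , drop = FALSE] - vertices[faces[, 1L], , drop = FALSE]
  e2 <- vertices[faces[, 3L], , drop = FALSE] - vertices[faces[, 1L], , drop = FALSE]
  cx <- e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L]
  cy <- e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L]
  cz <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Icosphere mesh
#'
#' Builds a geodesic sphere by recursive 4-way subdivision of a regular
#' icosahedron with projection onto the sphere. After `n` subdivisions the
#' mesh has `10 * 4^n + 2` vertices and `20 * 4^n` faces.
#'
#' @param subdivisions integer >= 0, number of subdivision rounds.
#' @param radius sphere radius in mm.
#' @return a `surface_mesh`.
#' @export
icosphere <- function(subdivisions = 3L, radius = 1) {
  stopifnot(subdivisions >= 0L, radius > 0)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    nf <- nrow(f)
    # midpoint vertex index for each undirected edge
    ea <- pmin(f[, c(1, 2, 3)], f[, c(2, 3, 1)])
    eb <- pmax(f[, c(1, 2, 3)], f[, c(2, 3, 1)])
    ekey <- paste(ea, eb)
    uk <- !duplicated(as.vector(ekey))
    key_id <- match(as.vector(ekey), as.vector(ekey)[uk])
    mids <- (v[as.vector(ea)[uk], , drop = FALSE] + v[as.vector(eb)[uk], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    mid_idx <- matrix(nv + key_id, nrow = nf)  # columns: mid(1,2), mid(2,3), mid(3,1)
    f <- rbind(
      cbind(f[, 1L], mid_idx[, 1L], mid_idx[, 3L]),
      cbind(f[, 2L], mid_idx[, 2L], mid_idx[, 1L]),
      cbind(f[, 3L], mid_idx[, 3L], mid_idx[, 2L]),
      mid_idx)
  }
  surface_mesh(v * radius, f)
}

#' Unique undirected edges of a mesh
#'
#' @param mesh a `surface_mesh`.
#' @return two-column integer matrix of 1-based vertex index pairs (i < j).
#' @export
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  e[!duplicated(e), , drop = FALSE]
}

#' Weighted edge graph of a mesh
#'
#' Undirected igraph whose edge weights are Euclidean edge lengths (mm); used
#' for geodesic distances and cluster connectivity.
#'
#' @param mesh a `surface_mesh`.
#' @return an `igraph` object with a `weight` edge attribute.
#' @export
mesh_graph <- function(mesh) {
  e <- mesh_edges(mesh)
  len <- sqrt(rowSums((mesh$vertices[e[, 1L], , drop = FALSE] -
                       mesh$vertices[e[, 2L], , drop = FALSE])^2))
  g <- igraph::make_graph(as.vector(t(e)), n = nrow(mesh$vertices), directed = FALSE)
  igraph::E(g)$weight <- len
  g
}

#' Euler characteristic V - E + F
#'
#' @param mesh a `surface_mesh`.
#' @return integer; 2 for any closed genus-0 surface.
#' @export
euler_characteristic <- function(mesh) {
  nrow(mesh$vertices) - nrow(mesh_edges(mesh)) + nrow(mesh$faces)
}

#' Outward vertex normals
#'
#' Area-weighted average of incident face normals, normalized to unit length.
#'
#' @param mesh a `surface_mesh`.
#' @return N x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  fn <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
              e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
              e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  n <- matrix(0, nrow(v), 3L)
  for (k in 1:3) {
    for (d in 1:3) {
      acc <- rowsum(fn[, d], group = f[, k], reorder = FALSE)
      n[as.integer(rownames(acc)), d] <- n[as.integer(rownames(acc)), d] + acc[, 1L]
    }
  }
  n / sqrt(rowSums(n^2))
}

#' Per-vertex surface areas
#'
#' Each vertex receives one third of the area of every incident triangle, so
#' vertex areas sum to the total mesh area. Used for cluster areas in mm^2.
#'
#' @param mesh a `surface_mesh`.
#' @return numeric vector of vertex areas (mm^2).
#' @export
vertex_areas <- function(mesh) {
  a <- triangle_areas(mesh$vertices, mesh$faces)
  out <- numeric(nrow(mesh$vertices))
  for (k in 1:3) {
    acc <- rowsum(a / 3, group = mesh$faces[, k], reorder = FALSE)
    idx <- as.integer(rownames(acc))
    out[idx] <- out[idx] + acc[, 1L]
  }
  out
}

#' Geodesic cap around a seed vertex
#'
#' Vertices whose shortest edge-path (geodesic) distance from the seed is at
#' most `radius_mm`; used to define phantom effect regions.
#'
#' @param mesh a `surface_mesh`.
#' @param seed_vertex 1-based vertex index.
#' @param radius_mm geodesic radius in mm.
#' @param graph optional precomputed [mesh_graph()].
#' @return integer vector of member vertex indices (includes the seed).
#' @export
geodesic_cap <- function(mesh, seed_vertex, radius_mm, graph = NULL) {
  stopifnot(seed_vertex >= 1L, seed_vertex <= nrow(mesh$vertices), radius_mm >= 0)
  if (is.null(graph)) graph <- mesh_graph(mesh)
  d <- as.vector(igraph::distances(graph, v = seed_vertex))
  which(d <= radius_mm)
}
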