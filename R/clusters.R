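# Cluster-wise inference on the mesh: suprathreshold connected components,
# Monte Carlo null distribution of the maximum cluster area, and family-wise
# error corrected cluster p-values.

#' Extract suprathreshold clusters
#'
#' The suprathreshold set is `{v : p_v < alpha_forming}`, split by the sign of
#' the t statistic (positive and negative effects never merge); its maximal
#' connected components under shared-mesh-edge connectivity are the clusters.
#' Cluster area is the sum of member vertex areas (mm^2).
#'
#' @param mesh a [surface_mesh()].
#' @param pmap per-vertex p-values (`NA` = not analyzed).
#' @param tmap per-vertex t statistics (sign used to split clusters).
#' @param alpha_forming cluster-forming threshold on the vertex p-values.
#' @param areas optional precomputed [vertex_areas()].
#' @param graph optional precomputed [mesh_graph()].
#' @return object of class `cluster_result`: a data frame `clusters` with
#'   columns `id, sign, n_vertices, area_mm2, peak_vertex, peak_t` (and later
#'   `p_fwe`, `significant`), plus `members`, a list of member vertex ids.
#' @export
cluster_extract <- function(mesh, pmap, tmap, alpha_forming,
                            areas = NULL, graph = NULL) {
  nv <- nrow(mesh$vertices)
  if (length(pmap) != nv || length(tmap) != nv)
    stop("maps do not align with the mesh")
  stopifnot(alpha_forming > 0, alpha_forming < 1)
  if (is.null(areas)) areas <- vertex_areas(mesh)
  supra <- which(!is.na(pmap) & pmap < alpha_forming & !is.na(tmap))
  empty <- list(
    clusters = data.frame(id = integer(0), sign = integer(0),
                          n_vertices = integer(0), area_mm2 = numeric(0),
                          peak_vertex = integer(0), peak_t = numeric(0)),
    members = list(), alpha_forming = alpha_forming, n_vertices = nv)
  if (!length(supra)) return(structure(empty, class = "cluster_result"))

  if (is.null(graph)) graph <- mesh_graph(mesh)
  members <- list()
  tab <- empty$clusters
  id <- 0L
  for (sgn in c(1, -1)) {
    vs <- supra[sign(tmap[supra]) == sgn]
    if (!length(vs)) next
    sub <- igraph::induced_subgraph(graph, vs)
    comp <- igraph::components(sub)
    for (ci in seq_len(comp$no)) {
      vids <- vs[comp$membership == ci]
      id <- id + 1L
      pk <- vids[which.max(abs(tmap[vids]))]
      members[[id]] <- sort(vids)
      tab <- rbind(tab, data.frame(
        id = id, sign = as.integer(sgn), n_vertices = length(vids),
        area_mm2 = sum(areas[vids]), peak_vertex = pk, peak_t = tmap[pk]))
    }
  }
  ord <- order(-tab$area_mm2)
  tab <- tab[ord, , drop = FALSE]
  members <- members[ord]
  tab$id <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(clusters = tab, members = members,
                 alpha_forming = alpha_forming, n_vertices = nv),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d cluster(s) at alpha = %g\n",
              nrow(x$clusters), x$alpha_forming))
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE)
  invisible(x)
}

# Adjacency list of the mesh (list of integer neighbor vectors); fast path
# for repeated component labeling inside the Monte Carlo loop.
adjacency_list <- function(mesh) {
  e <- mesh_edges(mesh)
  nv <- nrow(mesh$vertices)
  adj <- split(c(e[, 2L], e[, 1L]), factor(c(e[, 1L], e[, 2L]), levels = seq_len(nv)))
  unname(adj)
}

# Maximum cluster area of a suprathreshold vertex set, by BFS component
# labeling restricted to the set. Used by the Monte Carlo null.
max_component_area <- function(supra, adj, areas) {
  if (!length(supra)) return(0)
  in_set <- logical(length(adj))
  in_set[supra] <- TRUE
  seen <- logical(length(adj))
  best <- 0
  for (s in supra) {
    if (seen[s]) next
    queue <- s
    seen[s] <- TRUE
    total <- 0
    while (length(queue)) {
      v <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      total <- total + areas[v]
      nb <- adj[[v]]
      nb <- nb[in_set[nb] & !seen[nb]]
      if (length(nb)) {
        seen[nb] <- TRUE
        queue <- c(queue, nb)
      }
    }
    if (total > best) best <- total
  }
  best
}

#' Monte Carlo null distribution of the maximum cluster area
#'
#' Per repeat: draw an independent standard-normal deviate at every vertex,
#' smooth it with the analysis kernel, re-standardize the smoothed field to
#' zero mean and unit variance empirically, convert to two-sided normal
#' p-values, extract sign-split clusters at the forming threshold, and record
#' the maximum cluster area (0 when no vertex survives). Comparing observed
#' cluster areas against these maxima controls the family-wise error over the
#' whole surface.
#'
#' @param mesh a [surface_mesh()].
#' @param fwhm smoothing kernel FWHM (mm); must match the analysis smoothing.
#' @param alpha_forming cluster-forming threshold.
#' @param n_sims number of repeats (>= 100; the study-scale default is
#'   10,000).
#' @param seed integer seed; the returned distribution is deterministic given
#'   the seed.
#' @param kernel,graph,areas optional precomputed mesh quantities.
#' @return numeric vector of `n_sims` maximum cluster areas (mm^2), with the
#'   seed and parameters stored as attributes.
#' @export
monte_carlo_null <- function(mesh, fwhm, alpha_forming, n_sims = 10000L,
                             seed = NULL, kernel = NULL, graph = NULL,
                             areas = NULL) {
  if (fwhm < 0) stop("fwhm must be non-negative")
  stopifnot(alpha_forming > 0, alpha_forming < 1)
  n_sims <- as.integer(n_sims)
  if (n_sims < 100L) stop("n_sims must be at least 100")
  nv <- nrow(mesh$vertices)
  if (fwhm > 0 && is.null(kernel)) kernel <- smoothing_kernel(mesh, fwhm, graph)
  if (is.null(areas)) areas <- vertex_areas(mesh)
  adj <- adjacency_list(mesh)
  zcrit <- stats::qnorm(1 - alpha_forming / 2)

  with_seed(seed, {
    out <- numeric(n_sims)
    batch <- max(1L, min(n_sims, as.integer(2e7 / nv)))
    done <- 0L
    while (done < n_sims) {
      nb <- min(batch, n_sims - done)
      G <- matrix(stats::rnorm(nv * nb), nv, nb)
      Z <- if (fwhm > 0) {
        den <- as.vector(kernel %*% rep(1, nv))
        as.matrix(kernel %*% G) / den
      } else G
      Z <- scale(Z)  # empirical re-standardization per repeat
      for (j in seq_len(nb)) {
        z <- Z[, j]
        pos <- which(z > zcrit)
        neg <- which(z < -zcrit)
        out[done + j] <- max(max_component_area(pos, adj, areas),
                             max_component_area(neg, adj, areas))
      }
      done <- done + nb
    }
    structure(out, seed = seed, fwhm = fwhm, alpha_forming = alpha_forming,
              n_vertices = nv)
  })
}

#' Cluster-wise FWE-corrected p-values
#'
#' For each observed cluster,
#' `p_fwe = (1 + #{null maxima >= cluster area}) / (n_sims + 1)` (the add-one
#' Monte Carlo estimator, never exactly zero). Clusters with
#' `p_fwe < fwe_alpha` are flagged significant.
#'
#' @param observed a [cluster_extract()] result.
#' @param null numeric vector of null maximum cluster areas from
#'   [monte_carlo_null()].
#' @param fwe_alpha family-wise error level (default 0.05).
#' @return the `cluster_result` with `p_fwe` and `significant` columns added.
#' @export
cluster_fwe <- function(observed, null, fwe_alpha = 0.05) {
  stopifnot(inherits(observed, "cluster_result"))
  null <- as.numeric(null)
  if (!length(null)) stop("null distribution is empty")
  tab <- observed$clusters
  if (nrow(tab)) {
    tab$p_fwe <- vapply(tab$area_mm2, function(a)
      (1 + sum(null >= a)) / (length(null) + 1), numeric(1))
    tab$significant <- tab$p_fwe < fwe_alpha
  } else {
    tab$p_fwe <- numeric(0)
    tab$significant <- logical(0)
  }
  observed$clusters <- tab
  observed$fwe_alpha <- fwe_alpha
  observed$n_null <- length(null)
  observed
}

#' Vertices belonging to significant clusters
#'
#' @param result a [cluster_fwe()] result.
#' @return sorted integer vector of vertex ids in FWE-significant clusters.
#' @export
significant_vertices <- function(result) {
  stopifnot(inherits(result, "cluster_result"))
  if (is.null(result$clusters$significant)) stop("run cluster_fwe() first")
  keep <- which(result$clusters$significant)
  if (!length(keep)) return(integer(0))
  sort(unique(unlist(result$members[keep])))
}
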