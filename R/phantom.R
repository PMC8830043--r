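# Spherical cortical phantom: an icosphere white surface, a pial surface
# displaced radially by the cortical thickness, and a volumetric tensor field
# with an isotropic cortical ribbon, anisotropic white matter interior and
# empty exterior. The sphere preserves everything the pipeline measures
# (ribbon geometry, areas, mesh connectivity) while keeping vertex
# correspondence and region definitions trivial.

#' Phantom specification
#'
#' @param icosphere_subdivisions integer >= 2; controls mesh resolution
#'   (`10 * 4^n + 2` vertices).
#' @param white_radius white-surface radius, mm.
#' @param baseline_thickness cortical thickness in unaffected cortex, mm.
#' @param ribbon_md baseline cortical mean diffusivity, mm^2/s. Must lie in
#'   (0, 4e-3); the default 0.8e-3 is typical of healthy cortical gray matter.
#' @param wm_tensor_eigenvalues length-3 eigenvalues of the white-matter
#'   tensor, mm^2/s (principal axis oriented radially).
#' @param voxel_size isotropic voxel size of the simulated grid, mm.
#' @param s0 non-diffusion-weighted signal amplitude (arbitrary units).
#' @param noise_sigma Rician noise scale for DWI synthesis (signal units);
#'   0 gives noiseless data for exactness tests.
#' @param grid_margin margin (in voxels) added around the pial surface.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(icosphere_subdivisions = 3L,
                         white_radius = 50,
                         baseline_thickness = 2.5,
                         ribbon_md = 0.8e-3,
                         wm_tensor_eigenvalues = c(1.7e-3, 0.3e-3, 0.3e-3),
                         voxel_size = 2.7,
                         s0 = 1000,
                         noise_sigma = 0,
                         grid_margin = 2L) {
  stopifnot(icosphere_subdivisions >= 2L,
            white_radius > 0,
            baseline_thickness > 0,
            ribbon_md > 0, ribbon_md < 4e-3,
            length(wm_tensor_eigenvalues) == 3L,
            all(wm_tensor_eigenvalues > 0),
            voxel_size > 0, s0 > 0, noise_sigma >= 0)
  structure(list(icosphere_subdivisions = as.integer(icosphere_subdivisions),
                 white_radius = white_radius,
                 baseline_thickness = baseline_thickness,
                 ribbon_md = ribbon_md,
                 wm_tensor_eigenvalues = wm_tensor_eigenvalues,
                 voxel_size = voxel_size,
                 s0 = s0,
                 noise_sigma = noise_sigma,
                 grid_margin = as.integer(grid_margin)),
            class = "phantom_spec")
}

#' Regional effect specification
#'
#' Encodes the structure of the injected disease effect: an "atrophy core"
#' with both cortical thinning and mean-diffusivity elevation, a wider
#' "MD-only halo" with diffusivity elevation but no thinning, an optional
#' thickness-only control region, and a severity scaling shared by all
#' effects.
#'
#' @param core_region integer vertex ids receiving thinning and the full MD
#'   elevation.
#' @param halo_region integer vertex ids receiving MD elevation only (a
#'   superset of the core is allowed; effects are not double-counted).
#' @param thickness_reduction cortical thinning applied in the core (and in
#'   `ct_only_region`), mm; must be smaller than the baseline thickness of the
#'   phantom it is applied to.
#' @param md_elevation MD elevation applied in core and halo, mm^2/s.
#' @param md_elevation_core_extra additional MD elevation in the core only,
#'   mm^2/s, so the core can carry a larger standardized effect than the halo.
#' @param ct_only_region optional vertex ids receiving thinning but no MD
#'   change (control region for the net effect-size sign).
#' @param severity_slope relative effect scaling per severity point: a
#'   subject's effects are multiplied by
#'   `1 + severity_slope * (severity - group mean severity)`.
#' @return object of class `effect_spec`.
#' @export
effect_spec <- function(core_region = integer(0),
                        halo_region = integer(0),
                        thickness_reduction = 0,
                        md_elevation = 0,
                        md_elevation_core_extra = 0,
                        ct_only_region = integer(0),
                        severity_slope = 0) {
  stopifnot(thickness_reduction >= 0, md_elevation >= 0,
            md_elevation_core_extra >= 0)
  structure(list(core_region = as.integer(core_region),
                 halo_region = as.integer(halo_region),
                 thickness_reduction = thickness_reduction,
                 md_elevation = md_elevation,
                 md_elevation_core_extra = md_elevation_core_extra,
                 ct_only_region = as.integer(ct_only_region),
                 severity_slope = severity_slope),
            class = "effect_spec")
}

check_effect_regions <- function(effect, n_vertices) {
  rr <- c(effect$core_region, effect$halo_region, effect$ct_only_region)
  if (length(rr) && (min(rr) < 1L || max(rr) > n_vertices))
    stop("effect regions reference vertices outside the mesh")
  invisible(TRUE)
}

#' Build the white/pial surface pair of a phantom
#'
#' The white surface is an icosphere of the requested radius; pial vertices
#' are the white vertices displaced outward along the (exactly radial) vertex
#' normals by the baseline thickness. Face lists are shared, so vertex
#' correspondence is 1:1 by construction.
#'
#' @param spec a [phantom_spec()].
#' @param thickness optional per-vertex thickness vector (mm) overriding the
#'   uniform baseline (used for subjects with regional thinning).
#' @return a [surface_pair()].
#' @export
make_surface_pair <- function(spec, thickness = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  white <- icosphere(spec$icosphere_subdivisions, spec$white_radius)
  if (is.null(thickness)) thickness <- rep(spec$baseline_thickness, nrow(white$vertices))
  if (length(thickness) != nrow(white$vertices))
    stop("thickness vector length does not match vertex count")
  if (any(thickness < 0)) stop("negative thickness")
  normals <- white$vertices / spec$white_radius  # exact sphere normals
  pial <- surface_mesh(white$vertices + normals * thickness, white$faces,
                       check = FALSE)
  surface_pair(white, pial)
}

#' Per-vertex effect maps implied by an effect specification
#'
#' @param effect an [effect_spec()].
#' @param n_vertices mesh vertex count.
#' @param scale per-subject severity scaling factor (default 1).
#' @return list with `md_elevation` and `thickness_reduction` vertex vectors.
#' @export
effect_maps <- function(effect, n_vertices, scale = 1) {
  check_effect_regions(effect, n_vertices)
  md <- numeric(n_vertices)
  md[effect$halo_region] <- effect$md_elevation
  md[effect$core_region] <- effect$md_elevation + effect$md_elevation_core_extra
  th <- numeric(n_vertices)
  th[effect$core_region] <- effect$thickness_reduction
  th[effect$ct_only_region] <- effect$thickness_reduction
  list(md_elevation = md * scale, thickness_reduction = th * scale)
}

#' Volumetric tensor field of the phantom
#'
#' Voxels whose centers lie radially between the white and pial surfaces carry
#' an isotropic tensor with MD equal to the per-vertex MD of the nearest mesh
#' vertex (baseline ribbon MD plus any injected elevation); voxels inside the
#' white surface carry the anisotropic white-matter tensor with its principal
#' axis oriented radially; exterior voxels carry a zero tensor and are marked
#' invalid.
#'
#' @param spec a [phantom_spec()].
#' @param pair the subject's [surface_pair()] (its per-vertex thickness
#'   defines the outer ribbon boundary).
#' @param effect optional [effect_spec()] adding MD elevation.
#' @param subject_md_map optional per-vertex absolute MD (mm^2/s) overriding
#'   `ribbon_md` + effect.
#' @param effect_scale severity scaling passed to [effect_maps()].
#' @param dims,affine optional explicit grid (3 dimensions and 4 x 4
#'   voxel-to-world affine); the default grid is sized to contain the pial
#'   surface with a margin. An explicit grid that does not fully contain the
#'   pial surface is an error.
#' @return a [tensor_volume()].
#' @export
make_tensor_volume <- function(spec, pair, effect = NULL, subject_md_map = NULL,
                               effect_scale = 1, dims = NULL, affine = NULL) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(pair, "surface_pair"))
  nv <- nrow(pair$white$vertices)
  thickness <- cortical_thickness(pair)
  if (is.null(subject_md_map)) {
    md_v <- rep(spec$ribbon_md, nv)
    if (!is.null(effect))
      md_v <- md_v + effect_maps(effect, nv, effect_scale)$md_elevation
  } else {
    if (length(subject_md_map) != nv) stop("subject_md_map length mismatch")
    md_v <- subject_md_map
  }

  r_out_max <- max(sqrt(rowSums(pair$pial$vertices^2)))
  if (is.null(dims) != is.null(affine))
    stop("dims and affine must be supplied together")
  if (is.null(dims)) {
    extent <- 2 * (r_out_max + spec$grid_margin * spec$voxel_size)
    dims <- rep(ceiling(extent / spec$voxel_size) + 1L, 3L)
    affine <- centered_affine(dims, spec$voxel_size)
  }
  dims <- as.integer(dims)
  vox <- cbind(pair$pial$vertices, 1) %*% t(solve(affine))
  inside <- vox[, 1:3] >= 0 & sweep(vox[, 1:3], 2L, dims - 1L, "<=")
  if (!all(inside))
    stop("voxel grid too small to contain the pial surface")

  centers <- voxel_centers(dims, affine)
  r <- sqrt(rowSums(centers^2))
  nvox <- nrow(centers)

  D <- matrix(0, nvox, 6L)
  valid <- rep(FALSE, nvox)

  # interior white matter: radially oriented cylindrically symmetric tensor
  # D = l2 * I + (l1 - l2) * u u^T with u the radial unit vector
  ev <- spec$wm_tensor_eigenvalues
  interior <- which(r < spec$white_radius)
  if (length(interior)) {
    u <- centers[interior, , drop = FALSE] / pmax(r[interior], 1e-12)
    dl <- ev[1L] - ev[2L]
    D[interior, 1L] <- ev[2L] + dl * u[, 1L]^2
    D[interior, 2L] <- ev[2L] + dl * u[, 2L]^2
    D[interior, 3L] <- ev[2L] + dl * u[, 3L]^2
    D[interior, 4L] <- dl * u[, 1L] * u[, 2L]
    D[interior, 5L] <- dl * u[, 1L] * u[, 3L]
    D[interior, 6L] <- dl * u[, 2L] * u[, 3L]
    valid[interior] <- TRUE
  }

  # shell voxels: nearest vertex by direction, ribbon test against that
  # vertex's thickness
  shell <- which(r >= spec$white_radius & r <= r_out_max)
  if (length(shell)) {
    u <- centers[shell, , drop = FALSE] / r[shell]
    vunit <- pair$white$vertices / spec$white_radius
    nearest <- integer(length(shell))
    step <- 20000L
    for (i0 in seq(1L, length(shell), by = step)) {
      i1 <- min(i0 + step - 1L, length(shell))
      dots <- u[i0:i1, , drop = FALSE] %*% t(vunit)
      nearest[i0:i1] <- max.col(dots, ties.method = "first")
    }
    in_ribbon <- r[shell] <= spec$white_radius + thickness[nearest]
    rib <- shell[in_ribbon]
    mdv <- md_v[nearest[in_ribbon]]
    D[rib, 1L] <- mdv
    D[rib, 2L] <- mdv
    D[rib, 3L] <- mdv
    valid[rib] <- TRUE
  }

  log_s0 <- array(ifelse(valid, log(spec$s0), -Inf), dims)
  tensor_volume(D = array(D, c(dims, 6L)),
                log_s0 = log_s0,
                affine = affine,
                valid = array(valid, dims))
}
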