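# Synthetic multi-site cohort with known ground truth. Group sizes, severity
# distributions and covariate frequencies emulate a multicenter PPA
# case-control study: 52 non-fluent, 31 semantic and 32 logopenic variant
# patients plus 5 GRN-mutation carriers and 89 controls across three sites.

#' Cohort design
#'
#' @param n_control,n_nfvppa,n_svppa,n_lvppa,n_ppa_grn group sizes; the
#'   defaults reproduce the reference multicenter cohort (209 participants).
#' @param sites character vector of site labels (default three sites).
#' @param site_probs sampling probabilities per site.
#' @param age_mean,age_sd age distribution (years).
#' @param female_prob probability of `sex == "F"`.
#' @param left_handed_prob probability of `handedness == "L"`.
#' @param severity_mean,severity_sd per-group mean (SD) of the severity
#'   sum-of-boxes score (0-24 scale, CDR-plus-NACC-FTLD-SB-like); controls
#'   are always 0.
#' @param mild_prob per-group probability of a global disease stage of 0.5
#'   ("mild"); mild patients draw severity from the lower part of the scale.
#' @param mmse_mean,mmse_sd per-group MMSE distribution (0-30).
#' @return object of class `cohort_design`.
#' @export
cohort_design <- function(n_control = 89L, n_nfvppa = 52L, n_svppa = 31L,
                          n_lvppa = 32L, n_ppa_grn = 5L,
                          sites = c("siteA", "siteB", "siteC"),
                          site_probs = c(0.4, 0.35, 0.25),
                          age_mean = 67, age_sd = 7.5,
                          female_prob = 0.55,
                          left_handed_prob = 0.1,
                          severity_mean = c(nfvppa = 3.9, svppa = 6.3,
                                            lvppa = 5.1, `ppa-grn` = 3.8),
                          severity_sd = c(nfvppa = 2.6, svppa = 3.2,
                                          lvppa = 2.8, `ppa-grn` = 3.0),
                          mild_prob = c(nfvppa = 0.38, svppa = 0.19,
                                        lvppa = 0.28, `ppa-grn` = 0.2),
                          mmse_mean = c(control = 29.1, nfvppa = 25.0,
                                        svppa = 23.9, lvppa = 20.7,
                                        `ppa-grn` = 27.0),
                          mmse_sd = c(control = 0.9, nfvppa = 4.6,
                                      svppa = 4.6, lvppa = 6.2,
                                      `ppa-grn` = 2.6)) {
  stopifnot(length(sites) >= 1L, length(site_probs) == length(sites),
            all(site_probs > 0))
  structure(list(n = c(control = as.integer(n_control),
                       nfvppa = as.integer(n_nfvppa),
                       svppa = as.integer(n_svppa),
                       lvppa = as.integer(n_lvppa),
                       `ppa-grn` = as.integer(n_ppa_grn)),
                 sites = sites, site_probs = site_probs / sum(site_probs),
                 age_mean = age_mean, age_sd = age_sd,
                 female_prob = female_prob,
                 left_handed_prob = left_handed_prob,
                 severity_mean = severity_mean, severity_sd = severity_sd,
                 mild_prob = mild_prob,
                 mmse_mean = mmse_mean, mmse_sd = mmse_sd),
            class = "cohort_design")
}

#' Site effect specification
#'
#' Additive (location) and multiplicative (residual variance) scanner effects
#' injected on the MD field before any measurement, emulating how site
#' differences arise physically.
#'
#' @param sites character site labels.
#' @param additive_shift per-site additive MD shift, mm^2/s.
#' @param variance_scale per-site multiplicative factor (> 0) on the residual
#'   *variance* (noise SD is scaled by its square root).
#' @return object of class `site_effect_spec`.
#' @export
site_effect_spec <- function(sites = c("siteA", "siteB", "siteC"),
                             additive_shift = c(0, 4e-5, -3e-5),
                             variance_scale = c(1, 1.3, 0.8)) {
  stopifnot(length(additive_shift) == length(sites),
            length(variance_scale) == length(sites),
            all(variance_scale > 0))
  structure(list(sites = sites,
                 additive_shift = stats::setNames(additive_shift, sites),
                 variance_scale = stats::setNames(variance_scale, sites)),
            class = "site_effect_spec")
}

#' Default phantom effect regions and magnitudes
#'
#' A geodesic-cap "atrophy core" (thinning + MD elevation), a surrounding
#' MD-only halo, and an antipodal thickness-only control cap. Magnitudes are
#' calibrated so the injected standardized effects (relative to the
#' unsmoothed between-subject SD of the default noise model, see
#' [simulate_cohort()]) are about 1.2 in the core and 0.8 in the halo.
#'
#' @param mesh the phantom's white `surface_mesh`.
#' @param seed_vertex cap center (default vertex 1).
#' @param core_radius,halo_radius geodesic radii in mm.
#' @param ct_only_radius radius of the thickness-only control cap, centered on
#'   the vertex antipodal to `seed_vertex` (0 disables it).
#' @param graph optional precomputed [mesh_graph()].
#' @inheritParams effect_spec
#' @return an [effect_spec()].
#' @export
default_effect <- function(mesh, seed_vertex = 1L,
                           core_radius = 18, halo_radius = 60,
                           ct_only_radius = 15,
                           thickness_reduction = 0.6,
                           md_elevation = 0.2e-3,
                           md_elevation_core_extra = 0.1e-3,
                           severity_slope = 0.1,
                           graph = NULL) {
  if (is.null(graph)) graph <- mesh_graph(mesh)
  core <- geodesic_cap(mesh, seed_vertex, core_radius, graph)
  halo <- geodesic_cap(mesh, seed_vertex, halo_radius, graph)
  ct_only <- integer(0)
  if (ct_only_radius > 0) {
    anti <- which.min(as.vector(mesh$vertices %*% mesh$vertices[seed_vertex, ]))
    ct_only <- geodesic_cap(mesh, anti, ct_only_radius, graph)
    ct_only <- setdiff(ct_only, halo)
  }
  effect_spec(core_region = core, halo_region = halo,
              thickness_reduction = thickness_reduction,
              md_elevation = md_elevation,
              md_elevation_core_extra = md_elevation_core_extra,
              ct_only_region = ct_only,
              severity_slope = severity_slope)
}

draw_severity <- function(group, design) {
  if (group == "control") return(list(severity = 0, stage = 0))
  pm <- design$mild_prob[[group]]
  mild <- stats::runif(1) < pm
  if (mild) {
    s <- stats::rnorm(1, 2.5, 1)
    s <- min(max(s, 0.5), 4)
    list(severity = s, stage = 0.5)
  } else {
    s <- stats::rnorm(1, design$severity_mean[[group]] + 1.5,
                      design$severity_sd[[group]])
    s <- min(max(s, 4), 24)
    list(severity = s, stage = 1)
  }
}

#' Simulate a multi-site cohort with known ground truth
#'
#' Generates a cohort table, per-subject ground-truth MD and thickness vertex
#' maps (baseline plus severity-scaled regional effects, free of noise and
#' site effects), and observed per-subject maps with between-subject
#' variability and injected site effects. With `output = "dwi"` the observed
#' MD field of every subject is additionally pushed through the full forward
#' model (tensor volume + DWI synthesis), so the tensor-fitting and sampling
#' stages can be exercised end to end.
#'
#' The observation model per subject j at vertex v is
#' `md_obs = md_truth + shift_site + sqrt(scale_site) * (u_j + e_jv)` with a
#' subject-level random intercept `u_j` and independent vertex noise `e_jv`
#' (and analogously for thickness, without site effects). Patients' regional
#' effects are multiplied by `1 + severity_slope * (severity - group mean)`,
#' making the injected effect magnitude strictly monotone in severity while
#' keeping the group-mean effect equal to the nominal effect sizes.
#'
#' @param design a [cohort_design()].
#' @param phantom a [phantom_spec()].
#' @param effect an [effect_spec()] (e.g. [default_effect()]).
#' @param site_effects a [site_effect_spec()]; site labels must cover the
#'   design's sites.
#' @param seed integer seed; the whole cohort is reproducible given the seed.
#' @param output `"maps"` returns observed vertex maps only; `"dwi"` also
#'   returns per-subject `dwi_volume`s and `surface_pair`s.
#' @param md_subject_sd,md_vertex_sd between-subject random-intercept SD and
#'   vertex-level noise SD of the MD observations, mm^2/s.
#' @param ct_subject_sd,ct_vertex_sd same for thickness, mm.
#' @return object of class `cmd_cohort`: `cohort` (data frame with columns
#'   id, group, site, age, sex, handedness, severity, mmse, global_stage),
#'   observed matrices `md` and `thickness` (subjects x vertices),
#'   ground-truth matrices `md_truth` and `thickness_truth`, the baseline
#'   `pair`, the `effect`, and optionally `dwi` / `pairs` lists.
#' @export
simulate_cohort <- function(design, phantom, effect, site_effects,
                            seed = 1L, output = c("maps", "dwi"),
                            md_subject_sd = 0.02e-3, md_vertex_sd = 0.25e-3,
                            ct_subject_sd = 0.05, ct_vertex_sd = 0.5) {
  stopifnot(inherits(design, "cohort_design"),
            inherits(phantom, "phantom_spec"),
            inherits(effect, "effect_spec"),
            inherits(site_effects, "site_effect_spec"))
  output <- match.arg(output)
  unknown <- setdiff(design$sites, site_effects$sites)
  if (length(unknown))
    stop("unknown site label(s) in design: ", paste(unknown, collapse = ", "))
  groups <- names(design$n)[design$n > 0L]
  if (any(design$n[groups] < 2L))
    stop("each non-empty group needs at least 2 subjects")
  if (effect$thickness_reduction >= phantom$baseline_thickness)
    stop("thickness_reduction must be smaller than the baseline thickness")

  pair <- make_surface_pair(phantom)
  nv <- nrow(pair$white$vertices)
  check_effect_regions(effect, nv)

  with_seed(seed, {
    group <- factor(rep(groups, design$n[groups]),
                    levels = c("control", "nfvppa", "svppa", "lvppa", "ppa-grn"))
    group <- droplevels(group)
    ns <- length(group)
    id <- sprintf("sub-%03d", seq_len(ns))
    site <- sample(design$sites, ns, replace = TRUE, prob = design$site_probs)
    # guarantee at least two subjects per site
    for (s in design$sites) {
      short <- 2L - sum(site == s)
      if (short > 0) {
        donor <- names(sort(table(site), decreasing = TRUE))[1L]
        site[which(site == donor)[seq_len(short)]] <- s
      }
    }
    age <- round(stats::rnorm(ns, design$age_mean, design$age_sd), 1)
    sex <- ifelse(stats::runif(ns) < design$female_prob, "F", "M")
    handedness <- ifelse(stats::runif(ns) < design$left_handed_prob, "L", "R")
    sev <- t(vapply(as.character(group), function(g) {
      d <- draw_severity(g, design)
      c(d$severity, d$stage)
    }, numeric(2)))
    severity <- round(sev[, 1L] * 2) / 2  # half-point boxes
    stage <- sev[, 2L]
    mmse <- round(pmin(30, pmax(0, stats::rnorm(
      ns, design$mmse_mean[as.character(group)],
      design$mmse_sd[as.character(group)]))))

    cohort <- data.frame(id = id, group = group, site = site, age = age,
                         sex = sex, handedness = handedness,
                         severity = severity, mmse = mmse,
                         global_stage = stage, stringsAsFactors = FALSE)

    # severity scaling: group-mean-centered so the mean patient carries the
    # nominal effect and scaling is monotone in severity
    scale_j <- rep(0, ns)
    for (g in setdiff(levels(group), "control")) {
      rows <- which(group == g)
      s <- pmax(0, 1 + effect$severity_slope * (severity[rows] - mean(severity[rows])))
      scale_j[rows] <- s
    }

    base_md <- rep(phantom$ribbon_md, nv)
    base_th <- rep(phantom$baseline_thickness, nv)
    unit_maps <- effect_maps(effect, nv, scale = 1)

    md_truth <- matrix(rep(base_md, each = ns), ns, nv)
    th_truth <- matrix(rep(base_th, each = ns), ns, nv)
    md_truth <- md_truth + scale_j %o% unit_maps$md_elevation
    th_truth <- th_truth - scale_j %o% unit_maps$thickness_reduction
    if (any(th_truth <= 0)) stop("severity scaling drove thickness below zero")

    shift <- site_effects$additive_shift[site]
    sdscale <- sqrt(site_effects$variance_scale[site])
    u_md <- stats::rnorm(ns, 0, md_subject_sd)
    u_ct <- stats::rnorm(ns, 0, ct_subject_sd)
    e_md <- matrix(stats::rnorm(ns * nv, 0, md_vertex_sd), ns, nv)
    e_ct <- matrix(stats::rnorm(ns * nv, 0, ct_vertex_sd), ns, nv)
    md_obs <- md_truth + shift + sdscale * (u_md + e_md)
    th_obs <- th_truth + (u_ct + e_ct)

    rownames(md_obs) <- rownames(th_obs) <- id
    rownames(md_truth) <- rownames(th_truth) <- id

    out <- list(cohort = cohort, md = md_obs, thickness = th_obs,
                md_truth = md_truth, thickness_truth = th_truth,
                pair = pair, effect = effect, phantom = phantom,
                site_effects = site_effects, seed = seed,
                scale_j = scale_j)

    if (output == "dwi") {
      protocol <- default_protocol()
      pairs <- vector("list", ns)
      dwi <- vector("list", ns)
      for (j in seq_len(ns)) {
        pj <- make_surface_pair(phantom, thickness = pmax(th_truth[j, ], 0.1))
        tj <- make_tensor_volume(phantom, pj, subject_md_map = md_obs[j, ])
        dwi[[j]] <- simulate_dwi(tj, protocol, noise_sigma = phantom$noise_sigma,
                                 seed = seed + 1000L + j)
        pairs[[j]] <- pj
      }
      names(pairs) <- names(dwi) <- id
      out$pairs <- pairs
      out$dwi <- dwi
      out$protocol <- protocol
    }
    structure(out, class = "cmd_cohort")
  })
}

#' @export
print.cmd_cohort <- function(x, ...) {
  cat("cmd_cohort:", nrow(x$cohort), "subjects,",
      ncol(x$md), "vertices\n")
  print(table(x$cohort$group, x$cohort$site))
  invisible(x)
}
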