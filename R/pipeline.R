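# Orchestration of the full analysis: smoothing, harmonization, vertex-wise
# GLM, cluster-wise Monte Carlo FWE correction, effect-size and net
# effect-size maps, for group comparisons, mild-stage subgroup analyses, and
# severity/MMSE correlations.

#' Analysis configuration
#'
#' Defaults mirror the reference analysis: 15 mm FWHM smoothing, cluster
#' forming thresholds of 0.001 for whole-group comparisons and 0.05 for
#' subgroup and correlation analyses, FWE level 0.05 with 10,000 Monte Carlo
#' repeats, nuisance covariates age/sex/handedness for MD (site handled by
#' harmonization) plus site for thickness, and a mild-stage rule of a global
#' severity stage equal to 0.5.
#'
#' @param fwhm surface smoothing FWHM, mm.
#' @param alpha_forming_group cluster-forming threshold for whole-group
#'   comparisons.
#' @param alpha_forming_subgroup cluster-forming threshold for subgroup and
#'   correlation analyses.
#' @param fwe_alpha cluster-wise family-wise error level.
#' @param n_sims Monte Carlo repeats for the null distribution.
#' @param covariates_md nuisance covariates for MD models.
#' @param covariates_thickness nuisance covariates for thickness models.
#' @param harmonize_md harmonize MD across sites before analysis.
#' @param combat_covariates biological covariates preserved by harmonization.
#' @param mild_stage global severity stage defining the mild subgroup.
#' @param smooth_before_harmonization smooth MD maps before (default) or
#'   after ComBat.
#' @param seed integer seed for the Monte Carlo simulation.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(fwhm = 15,
                            alpha_forming_group = 0.001,
                            alpha_forming_subgroup = 0.05,
                            fwe_alpha = 0.05,
                            n_sims = 10000L,
                            covariates_md = c("age", "sex", "handedness"),
                            covariates_thickness = c("age", "sex", "handedness", "site"),
                            harmonize_md = TRUE,
                            combat_covariates = c("group", "age", "sex", "handedness"),
                            mild_stage = 0.5,
                            smooth_before_harmonization = TRUE,
                            seed = 1L) {
  stopifnot(fwhm >= 0,
            alpha_forming_group > 0, alpha_forming_group < 1,
            alpha_forming_subgroup > 0, alpha_forming_subgroup < 1,
            fwe_alpha > 0, fwe_alpha < 1,
            n_sims >= 100L)
  if (n_sims < 10000L)
    warning("n_sims = ", n_sims, " is below the study-scale default of 10,000",
            call. = FALSE)
  structure(list(fwhm = fwhm,
                 alpha_forming_group = alpha_forming_group,
                 alpha_forming_subgroup = alpha_forming_subgroup,
                 fwe_alpha = fwe_alpha, n_sims = as.integer(n_sims),
                 covariates_md = covariates_md,
                 covariates_thickness = covariates_thickness,
                 harmonize_md = harmonize_md,
                 combat_covariates = combat_covariates,
                 mild_stage = mild_stage,
                 smooth_before_harmonization = smooth_before_harmonization,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

# Numeric nuisance design from cohort columns (factors expanded to k-1
# indicators; intercept NOT included).
build_covariates <- function(cohort, vars) {
  if (!length(vars)) return(NULL)
  missing_vars <- setdiff(vars, names(cohort))
  if (length(missing_vars))
    stop("cohort table lacks covariate column(s): ",
         paste(missing_vars, collapse = ", "))
  d <- cohort[vars]
  for (v in vars) if (!is.numeric(d[[v]])) d[[v]] <- factor(d[[v]])
  # drop factors with a single level (e.g. one site after subsetting)
  keep <- vapply(d, function(x) !is.factor(x) || nlevels(droplevels(x)) > 1L,
                 logical(1))
  d <- d[keep]
  if (!ncol(d)) return(NULL)
  mm <- stats::model.matrix(~ ., data = droplevels(d))
  mm[, -1L, drop = FALSE]
}

check_inputs <- function(cohort, md, ct, mesh) {
  nv <- nrow(mesh$vertices)
  if (ncol(md) != nv || ncol(ct) != nv)
    stop("map vertex counts do not match the mesh")
  if (nrow(md) != nrow(cohort) || nrow(ct) != nrow(cohort))
    stop("map rows do not match the cohort table")
  req <- c("id", "group", "site")
  miss <- setdiff(req, names(cohort))
  if (length(miss)) stop("cohort table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(cohort$id)) stop("duplicate subject ids")
  invisible(TRUE)
}

prepare_metric <- function(Y, cohort, config, mesh, kernel, harmonize) {
  smooth_first <- config$smooth_before_harmonization
  if (smooth_first && config$fwhm > 0)
    Y <- smooth_matrix(mesh, Y, config$fwhm, kernel = kernel)
  if (harmonize && length(unique(cohort$site)) > 1L) {
    cov <- build_covariates(cohort, config$combat_covariates)
    model <- combat_fit(Y, cohort$site, covariates = cov)
    Y <- combat_apply(Y, model, cohort$site, covariates = cov)
  }
  if (!smooth_first && config$fwhm > 0)
    Y <- smooth_matrix(mesh, Y, config$fwhm, kernel = kernel)
  Y
}

analyze_metric <- function(Y, X, contrast, mesh, config, alpha_forming,
                           null_dist, areas, graph) {
  fit <- glm_fit(Y, X, contrast)
  clus <- cluster_extract(mesh, fit$p, fit$t, alpha_forming,
                          areas = areas, graph = graph)
  clus <- cluster_fwe(clus, null_dist, config$fwe_alpha)
  list(fit = fit, clusters = clus)
}

#' Two-group comparison of cortical thickness and mean diffusivity
#'
#' Runs the full vertex-wise comparison of `group_a` (e.g. a patient variant)
#' against `group_b` (e.g. controls): surface smoothing, MD harmonization
#' across sites, per-metric GLM with the metric's nuisance covariates,
#' cluster extraction with Monte Carlo FWE correction, Cohen's d maps, and
#' the net effect-size map over the union of FWE-significant vertices of
#' either metric. Positive t / positive d mean `group_a` larger than
#' `group_b`.
#'
#' @param cohort cohort data frame (columns id, group, site plus covariates).
#' @param md,ct subjects x vertices matrices of unsmoothed MD and thickness.
#' @param mesh the common `surface_mesh` (shared topology across subjects).
#' @param config an [analysis_config()].
#' @param group_a,group_b group labels to compare (t and d are a minus b).
#' @param alpha_forming override of the cluster-forming threshold (defaults
#'   to `config$alpha_forming_group`).
#' @param output_dir optional directory; when given, per-vertex maps, cluster
#'   tables and a JSON manifest are written via [write_analysis()].
#' @return object of class `cmd_analysis`.
#' @export
run_group_comparison <- function(cohort, md, ct, mesh, config,
                                 group_a, group_b = "control",
                                 alpha_forming = NULL,
                                 output_dir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  check_inputs(cohort, md, ct, mesh)
  if (is.null(alpha_forming)) alpha_forming <- config$alpha_forming_group
  sel <- cohort$group %in% c(group_a, group_b)
  if (sum(cohort$group == group_a) < 2L || sum(cohort$group == group_b) < 2L)
    stop("both groups must be present with at least 2 subjects")
  cohort_s <- droplevels(cohort[sel, , drop = FALSE])
  md_s <- md[sel, , drop = FALSE]
  ct_s <- ct[sel, , drop = FALSE]

  graph <- mesh_graph(mesh)
  areas <- vertex_areas(mesh)
  kernel <- if (config$fwhm > 0) smoothing_kernel(mesh, config$fwhm, graph) else NULL

  md_p <- prepare_metric(md_s, cohort_s, config, mesh, kernel,
                         harmonize = config$harmonize_md)
  ct_p <- prepare_metric(ct_s, cohort_s, config, mesh, kernel,
                         harmonize = FALSE)

  grp <- as.integer(cohort_s$group == group_a)
  X_md <- cbind(intercept = 1, group = grp,
                build_covariates(cohort_s, config$covariates_md))
  X_ct <- cbind(intercept = 1, group = grp,
                build_covariates(cohort_s, config$covariates_thickness))
  cvec <- function(X) c(0, 1, rep(0, ncol(X) - 2L))

  null_dist <- monte_carlo_null(mesh, config$fwhm, alpha_forming,
                                n_sims = config$n_sims, seed = config$seed,
                                kernel = kernel, graph = graph, areas = areas)

  res_md <- analyze_metric(md_p, X_md, cvec(X_md), mesh, config,
                           alpha_forming, null_dist, areas, graph)
  res_ct <- analyze_metric(ct_p, X_ct, cvec(X_ct), mesh, config,
                           alpha_forming, null_dist, areas, graph)

  gf <- factor(ifelse(grp == 1L, group_a, group_b), levels = c(group_a, group_b))
  d_md <- cohens_d(md_p, gf, nuisance = build_covariates(cohort_s, config$covariates_md))
  d_ct <- cohens_d(ct_p, gf, nuisance = build_covariates(cohort_s, config$covariates_thickness))

  sig_mask <- sort(union(significant_vertices(res_md$clusters),
                         significant_vertices(res_ct$clusters)))
  net <- net_effect_size(d_md, d_ct, sig_mask)

  manifest <- list(
    analysis = "group_comparison",
    groups = c(group_a = group_a, group_b = group_b),
    n_subjects = list(total_in = nrow(cohort), analyzed = nrow(cohort_s),
                      excluded = nrow(cohort) - nrow(cohort_s)),
    n_per_group = as.list(table(as.character(cohort_s$group))),
    n_vertices = nrow(mesh$vertices),
    n_vertices_analyzed_md = sum(!is.na(res_md$fit$t) | res_md$fit$degenerate),
    n_vertices_analyzed_ct = sum(!is.na(res_ct$fit$t) | res_ct$fit$degenerate),
    alpha_forming = alpha_forming,
    config = unclass(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("cortexmd")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  out <- structure(list(md = res_md, thickness = res_ct,
                        d_md = d_md, d_ct = d_ct,
                        net = net, sig_mask = sig_mask,
                        null_dist = null_dist,
                        config = config, manifest = manifest),
                   class = "cmd_analysis")
  if (!is.null(output_dir)) write_analysis(out, output_dir)
  out
}

#' @export
print.cmd_analysis <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("cmd_analysis: %s", m$analysis))
  if (!is.null(m$groups)) cat(sprintf(" (%s vs %s)", m$groups[1L], m$groups[2L]))
  if (!is.null(m$predictor)) cat(sprintf(" (predictor: %s)", m$predictor))
  cat(sprintf(", %d subjects\n", m$n_subjects[["analyzed"]]))
  for (metric in c("md", "thickness")) {
    cl <- x[[metric]]$clusters$clusters
    nsig <- if (nrow(cl)) sum(cl$significant) else 0L
    cat(sprintf("  %-9s: %d cluster(s), %d FWE-significant", metric,
                nrow(cl), nsig))
    if (nsig) {
      top <- cl[cl$significant, ][1L, ]
      cat(sprintf(" (largest %.0f mm^2, p_fwe = %.4g)", top$area_mm2, top$p_fwe))
    }
    cat("\n")
  }
  if (!is.null(x$net) && any(!is.na(x$net)))
    cat(sprintf("  net effect size over %d significant vertices: mean %.2f\n",
                sum(!is.na(x$net)), mean(x$net, na.rm = TRUE)))
  invisible(x)
}

#' Mild-stage subgroup comparison
#'
#' Restricts `group_a` to patients at the mild global disease stage
#' (`global_stage == config$mild_stage`) and delegates to
#' [run_group_comparison()] with the subgroup cluster-forming threshold
#' (default 0.05).
#'
#' @inheritParams run_group_comparison
#' @return a `cmd_analysis`.
#' @export
run_mild_subgroup <- function(cohort, md, ct, mesh, config,
                              group_a, group_b = "control",
                              output_dir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  if (!"global_stage" %in% names(cohort))
    stop("cohort table lacks a global_stage column")
  keep <- cohort$group != group_a |
    (!is.na(cohort$global_stage) & cohort$global_stage == config$mild_stage)
  if (!any(cohort$group == group_a & keep))
    stop("mild-stage rule excludes every ", group_a, " subject")
  res <- run_group_comparison(cohort[keep, , drop = FALSE],
                              md[keep, , drop = FALSE],
                              ct[keep, , drop = FALSE],
                              mesh, config, group_a, group_b,
                              alpha_forming = config$alpha_forming_subgroup,
                              output_dir = NULL)
  res$manifest$analysis <- "mild_subgroup"
  res$manifest$mild_stage <- config$mild_stage
  res$manifest$n_subjects <- list(total_in = nrow(cohort),
                                  analyzed = res$manifest$n_subjects[["analyzed"]],
                                  excluded = nrow(cohort) -
                                    res$manifest$n_subjects[["analyzed"]])
  if (!is.null(output_dir)) write_analysis(res, output_dir)
  res
}

#' Vertex-wise correlation with a severity or cognition score
#'
#' Within one patient group, regresses smoothed (and, for MD, harmonized)
#' maps on a continuous predictor (severity or MMSE) with the metric's
#' nuisance covariates, and applies cluster-wise FWE correction at the
#' subgroup forming threshold. The reported sign convention: positive t means
#' the metric increases with the predictor.
#'
#' @inheritParams run_group_comparison
#' @param predictor name of the cohort column used as predictor
#'   (e.g. `"severity"` or `"mmse"`).
#' @param group patient group analyzed (`NULL` = all non-control subjects).
#' @return a `cmd_analysis` with `md` and `thickness` correlation results and
#'   a `signs` summary.
#' @export
run_correlation <- function(cohort, md, ct, mesh, config,
                            predictor = "severity", group = NULL,
                            output_dir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  check_inputs(cohort, md, ct, mesh)
  if (!predictor %in% names(cohort))
    stop("cohort table lacks predictor column: ", predictor)
  sel <- if (is.null(group)) cohort$group != "control" else cohort$group %in% group
  if (!any(sel)) stop("no subjects selected for correlation analysis")
  cohort_s <- droplevels(cohort[sel, , drop = FALSE])
  x <- cohort_s[[predictor]]
  if (stats::var(x, na.rm = TRUE) == 0)
    stop("predictor '", predictor, "' is constant in the analyzed group")
  md_s <- md[sel, , drop = FALSE]
  ct_s <- ct[sel, , drop = FALSE]

  graph <- mesh_graph(mesh)
  areas <- vertex_areas(mesh)
  kernel <- if (config$fwhm > 0) smoothing_kernel(mesh, config$fwhm, graph) else NULL
  cfg_cb <- config
  cfg_cb$combat_covariates <- setdiff(config$combat_covariates, "group")
  md_p <- prepare_metric(md_s, cohort_s, cfg_cb, mesh, kernel,
                         harmonize = config$harmonize_md)
  ct_p <- prepare_metric(ct_s, cohort_s, config, mesh, kernel, harmonize = FALSE)

  alpha <- config$alpha_forming_subgroup
  null_dist <- monte_carlo_null(mesh, config$fwhm, alpha,
                                n_sims = config$n_sims, seed = config$seed,
                                kernel = kernel, graph = graph, areas = areas)

  fit_md <- correlation_analysis(md_p, x, build_covariates(cohort_s, config$covariates_md))
  fit_ct <- correlation_analysis(ct_p, x, build_covariates(cohort_s, config$covariates_thickness))
  cl_md <- cluster_fwe(cluster_extract(mesh, fit_md$p, fit_md$t, alpha,
                                       areas = areas, graph = graph),
                       null_dist, config$fwe_alpha)
  cl_ct <- cluster_fwe(cluster_extract(mesh, fit_ct$p, fit_ct$t, alpha,
                                       areas = areas, graph = graph),
                       null_dist, config$fwe_alpha)

  # direction of the detected effect: sign of t at the peak significant vertex
  sig_sign <- function(fit, cl) {
    v <- significant_vertices(cl)
    if (!length(v)) return(NA_real_)
    sign(fit$t[v][which.max(abs(fit$t[v]))])
  }
  signs <- c(md = sig_sign(fit_md, cl_md),
             thickness = sig_sign(fit_ct, cl_ct))

  manifest <- list(
    analysis = "correlation",
    predictor = predictor,
    group = if (is.null(group)) "all-patients" else group,
    n_subjects = list(total_in = nrow(cohort), analyzed = nrow(cohort_s),
                      excluded = nrow(cohort) - nrow(cohort_s)),
    n_vertices = nrow(mesh$vertices),
    alpha_forming = alpha,
    config = unclass(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("cortexmd")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  out <- structure(list(md = list(fit = fit_md, clusters = cl_md),
                        thickness = list(fit = fit_ct, clusters = cl_ct),
                        signs = signs, null_dist = null_dist,
                        config = config, manifest = manifest),
                   class = "cmd_analysis")
  if (!is.null(output_dir)) write_analysis(out, output_dir)
  out
}

#' Write an analysis bundle to a run directory
#'
#' Writes `maps/<metric>.csv` (per-vertex t, p, and where available d and
#' net), `clusters/<metric>.csv` cluster tables, and `manifest.json`.
#'
#' @param analysis a `cmd_analysis`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(analysis, dir) {
  stopifnot(inherits(analysis, "cmd_analysis"))
  dir.create(file.path(dir, "maps"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "clusters"), recursive = TRUE, showWarnings = FALSE)
  for (metric in c("md", "thickness")) {
    fit <- analysis[[metric]]$fit
    df <- data.frame(vertex_id = seq_along(fit$t), beta = fit$beta,
                     t = fit$t, p = fit$p)
    dname <- paste0("d_", if (metric == "md") "md" else "ct")
    if (!is.null(analysis[[dname]])) df$d <- as.numeric(analysis[[dname]])
    if (metric == "md" && !is.null(analysis$net)) df$net <- analysis$net
    utils::write.csv(df, file.path(dir, "maps", paste0(metric, ".csv")),
                     row.names = FALSE)
    utils::write.csv(analysis[[metric]]$clusters$clusters,
                     file.path(dir, "clusters", paste0(metric, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(analysis$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", force = TRUE)
  invisible(dir)
}
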