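# Synthetic cohort generator: sizes, determinism, ground-truth structure,
# severity monotonicity, and site-effect injection.

small_design <- function(...) cohort_design(n_control = 12, n_nfvppa = 12,
                                            n_svppa = 0, n_lvppa = 0,
                                            n_ppa_grn = 0, ...)

test_that("default design reproduces the reference cohort sizes", {
  phantom <- phantom_spec(icosphere_subdivisions = 2)
  mesh <- make_surface_pair(phantom)$white
  sim <- simulate_cohort(cohort_design(), phantom,
                         default_effect(mesh, halo_radius = 40),
                         site_effect_spec(), seed = 1)
  counts <- table(sim$cohort$group)
  expect_identical(as.integer(counts[c("control", "nfvppa", "svppa", "lvppa", "ppa-grn")]),
                   c(89L, 52L, 31L, 32L, 5L))
  expect_identical(nrow(sim$cohort), 209L)
  expect_false(anyDuplicated(sim$cohort$id) > 0)
  # controls carry zero severity and stage 0
  ctl <- sim$cohort$group == "control"
  expect_true(all(sim$cohort$severity[ctl] == 0))
  expect_true(all(sim$cohort$severity[!ctl] > 0))
  expect_true(all(sim$cohort$severity <= 24))
  expect_true(all(sim$cohort$mmse >= 0 & sim$cohort$mmse <= 30))
  expect_true(all(table(sim$cohort$site) >= 2))
})

test_that("the same seed reproduces the cohort byte for byte", {
  phantom <- phantom_spec(icosphere_subdivisions = 2)
  mesh <- make_surface_pair(phantom)$white
  eff <- default_effect(mesh, halo_radius = 40)
  a <- simulate_cohort(small_design(), phantom, eff, site_effect_spec(), seed = 7)
  b <- simulate_cohort(small_design(), phantom, eff, site_effect_spec(), seed = 7)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$md, b$md)
  expect_identical(a$thickness, b$thickness)
  cc <- simulate_cohort(small_design(), phantom, eff, site_effect_spec(), seed = 8)
  expect_false(identical(a$cohort, cc$cohort))
})

test_that("zero effects make patient and control ground truth identical", {
  phantom <- phantom_spec(icosphere_subdivisions = 2)
  eff0 <- effect_spec()
  sim <- simulate_cohort(small_design(), phantom, eff0, site_effect_spec(),
                         seed = 3)
  expect_true(all(sim$md_truth == phantom$ribbon_md))
  expect_true(all(sim$thickness_truth == phantom$baseline_thickness))
})

test_that("halo-only ground-truth MD differs by exactly the injected elevation", {
  phantom <- phantom_spec(icosphere_subdivisions = 2)
  mesh <- make_surface_pair(phantom)$white
  eff <- default_effect(mesh, halo_radius = 40)
  sim <- simulate_cohort(small_design(), phantom, eff, site_effect_spec(), seed = 5)
  halo_only <- setdiff(eff$halo_region, eff$core_region)
  pat <- sim$cohort$group != "control"
  gap <- mean(sim$md_truth[pat, halo_only]) - mean(sim$md_truth[!pat, halo_only])
  expect_equal(gap, eff$md_elevation, tolerance = 1e-12)
  core_gap <- mean(sim$md_truth[pat, eff$core_region]) -
    mean(sim$md_truth[!pat, eff$core_region])
  expect_equal(core_gap, eff$md_elevation + eff$md_elevation_core_extra,
               tolerance = 1e-12)
})

test_that("severity is monotone with the injected effect magnitude", {
  phantom <- phantom_spec(icosphere_subdivisions = 2)
  mesh <- make_surface_pair(phantom)$white
  eff <- default_effect(mesh, halo_radius = 40)
  des <- cohort_design(n_control = 5, n_nfvppa = 30, n_svppa = 0,
                       n_lvppa = 0, n_ppa_grn = 0)
  sim <- simulate_cohort(des, phantom, eff, site_effect_spec(), seed = 6)
  pat <- which(sim$cohort$group == "nfvppa")
  core_v <- eff$core_region[1]
  magnitude <- sim$md_truth[pat, core_v] - phantom$ribbon_md
  expect_equal(cor(sim$cohort$severity[pat], magnitude, method = "spearman"), 1)
})

test_that("site effects shift and rescale the observed MD per site", {
  phantom <- phantom_spec(icosphere_subdivisions = 2)
  se <- site_effect_spec(sites = c("siteA", "siteB", "siteC"),
                         additive_shift = c(0, 2e-4, 0),
                         variance_scale = c(1, 1, 3))
  des <- cohort_design(n_control = 120, n_nfvppa = 2, n_svppa = 0,
                       n_lvppa = 0, n_ppa_grn = 0)
  sim <- simulate_cohort(des, phantom, effect_spec(), se, seed = 9)
  ctl <- sim$cohort$group == "control"
  mA <- mean(sim$md[ctl & sim$cohort$site == "siteA", ])
  mB <- mean(sim$md[ctl & sim$cohort$site == "siteB", ])
  expect_lt(abs((mB - mA) - 2e-4), 3e-5)
  vA <- var(as.vector(sim$md[ctl & sim$cohort$site == "siteA", ]))
  vC <- var(as.vector(sim$md[ctl & sim$cohort$site == "siteC", ]))
  expect_equal(vC / vA, 3, tolerance = 0.4)
})

test_that("invalid labels and impossible effects are rejected", {
  phantom <- phantom_spec(icosphere_subdivisions = 2)
  mesh <- make_surface_pair(phantom)$white
  eff <- default_effect(mesh, halo_radius = 40)
  se2 <- site_effect_spec(sites = c("x", "y"), additive_shift = c(0, 0),
                          variance_scale = c(1, 1))
  expect_error(simulate_cohort(small_design(), phantom, eff, se2, seed = 1),
               "unknown site")
  des1 <- cohort_design(n_control = 12, n_nfvppa = 1, n_svppa = 0,
                        n_lvppa = 0, n_ppa_grn = 0)
  expect_error(simulate_cohort(des1, phantom, eff, site_effect_spec(), seed = 1),
               "at least 2")
  eff_bad <- default_effect(mesh, halo_radius = 40, thickness_reduction = 5)
  expect_error(simulate_cohort(small_design(), phantom, eff_bad,
                               site_effect_spec(), seed = 1),
               "baseline thickness")
})

test_that("the DWI output path reproduces the observed maps through the scanner model", {
  phantom <- phantom_spec(icosphere_subdivisions = 2, baseline_thickness = 3,
                          white_radius = 25, voxel_size = 1.3)
  mesh <- make_surface_pair(phantom)$white
  eff <- default_effect(mesh, core_radius = 10, halo_radius = 20,
                        ct_only_radius = 0)
  des <- cohort_design(n_control = 2, n_nfvppa = 2, n_svppa = 0,
                       n_lvppa = 0, n_ppa_grn = 0)
  sim <- simulate_cohort(des, phantom, eff, site_effect_spec(), seed = 13,
                         output = "dwi")
  expect_length(sim$dwi, 4L)
  j <- 3L  # a patient
  fit <- fit_tensor_loglinear(sim$dwi[[j]])
  md <- mean_diffusivity(fit)
  mid <- ribbon_midpoints(sim$pairs[[j]])
  sampled <- sample_volume_at_points(md, mid)
  ok <- !is.na(sampled)
  # midpoints of a 2.4-3 mm ribbon sampled on a 1.3 mm grid: a minority of
  # interpolation stencils touch invalid exterior voxels and stay missing
  expect_gt(mean(ok), 0.75)
  # noiseless chain: sampled MD approximates the subject's observed MD map,
  # up to trilinear blending with neighboring tissue
  expect_lt(median(abs(sampled[ok] - sim$md[j, ok])), 0.1e-3)
  expect_equal(cortical_thickness(sim$pairs[[j]]),
               pmax(sim$thickness_truth[j, ], 0.1), tolerance = 1e-9)
})
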