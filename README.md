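# cortexmd

Surface-based analysis of **cortical mean diffusivity** (cMD) and cortical
thickness for multi-center case-control neuroimaging studies.

In neurodegenerative syndromes such as primary progressive aphasia (PPA),
microstructural disorganization of the cortex — measurable as elevated mean
diffusivity, MD = trace(D)/3 of the diffusion tensor — can extend beyond, and
precede, macroscopic cortical thinning. Detecting that dissociation requires a
chain of steps, each of which this package implements and validates:

1. **Tensor fitting** — per-voxel OLS on the log signal model
   ln S(g, b) = ln S0 − b·gᵀDg (`fit_tensor_loglinear()`, `mean_diffusivity()`),
   exact on noiseless data.
2. **Ribbon sampling** — MD read at the midpoint of the cortical ribbon,
   m_v = (w_v + p_v)/2, by trilinear interpolation, minimizing partial-volume
   contamination (`ribbon_midpoints()`, `sample_volume_at_points()`); per-vertex
   thickness t_v = ‖p_v − w_v‖ (`cortical_thickness()`).
3. **Geodesic Gaussian smoothing** of vertex maps, FWHM 15 mm by default
   (`smooth_vertex_map()`).
4. **ComBat harmonization** — parametric empirical-Bayes removal of per-site
   additive (location) and multiplicative (scale) effects at every vertex,
   preserving modeled biological covariates (`combat_fit()`, `combat_apply()`).
5. **Vertex-wise GLM** with nuisance covariates, **Monte Carlo cluster-wise
   family-wise error correction** (max-cluster-area null from smoothed Gaussian
   noise, 10,000 repeats by default), **Cohen's d** maps, and the **net effect
   size** |d_MD| − |d_CT| over significant cortex (`glm_fit()`,
   `monte_carlo_null()`, `cluster_fwe()`, `cohens_d()`, `net_effect_size()`).
6. **Pipelines** for group comparisons, mild-stage subgroups, and
   severity/MMSE correlations (`run_group_comparison()`, `run_mild_subgroup()`,
   `run_correlation()`), writing per-vertex CSV maps, cluster tables, and a
   JSON manifest.

Because real multi-center MRI cannot ship with a package, `cortexmd` includes a
first-class **synthetic phantom generator**: icosphere white/pial pairs, a
volumetric tensor field with an isotropic cortical ribbon and anisotropic white
matter, DWI synthesis with Rician noise, and multi-site cohorts with a known
"atrophy core" (thinning + MD elevation), a wider "MD-only halo", severity
scores that scale the injected effects, and injected site effects
(`phantom_spec()`, `make_surface_pair()`, `make_tensor_volume()`,
`simulate_dwi()`, `simulate_cohort()`). Every stage is tested against this
ground truth. See the vignette `vignettes/cortical-md-pipeline.Rmd` for the
models, parameter defaults, and limitations.

## Worked example

Simulate 30 patients vs 30 controls on the default phantom and run the group
comparison:

```r
library(cortexmd)
phantom <- phantom_spec()                       # 642-vertex sphere, r = 50 mm
mesh    <- make_surface_pair(phantom)$white
effect  <- default_effect(mesh)                 # core 18 mm, halo 60 mm
design  <- cohort_design(n_control = 30, n_nfvppa = 30,
                         n_svppa = 0, n_lvppa = 0, n_ppa_grn = 0)
sim <- simulate_cohort(design, phantom, effect, site_effect_spec(), seed = 11)

cfg <- analysis_config(n_sims = 1000, seed = 1)
res <- run_group_comparison(sim$cohort, sim$md, sim$thickness, mesh, cfg, "nfvppa")
res
#> cmd_analysis: group_comparison (nfvppa vs control), 60 subjects
#>   md       : 2 cluster(s), 1 FWE-significant (largest 9547 mm^2, p_fwe = 0.000999)
#>   thickness: 2 cluster(s), 2 FWE-significant (largest 1062 mm^2, p_fwe = 0.000999)
#>   net effect size over 221 significant vertices: mean 1.56
```

The MD-significant cortex (9,547 mm²) is an order of magnitude larger than the
thickness-significant cortex (1,062 mm²): microstructural change extends far
beyond the atrophy core. Quantifying the dissociation against the known truth:

```r
halo_only <- setdiff(effect$halo_region, effect$core_region)
md_sig <- significant_vertices(res$md$clusters)
ct_sig <- significant_vertices(res$thickness$clusters)
100 * mean(halo_only %in% md_sig)   # 100  — halo fully inside MD clusters
100 * mean(halo_only %in% ct_sig)   # 2    — essentially absent from thickness clusters
mean(res$net[intersect(halo_only, res$sig_mask)])  # 2.12 — MD dominates the halo
```

`p_fwe = 0.000999` is the add-one Monte Carlo floor `1/(n_sims + 1)`: the
observed clusters exceed every null maximum.

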