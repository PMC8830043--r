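---
title: "Surface-based cortical mean diffusivity: models, parameters, and validation phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-based cortical mean diffusivity: models, parameters, and validation phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Cortical mean diffusivity (cMD) — the trace/3 of the diffusion tensor sampled
inside the cortical gray matter — is a microstructural marker that can become
abnormal before macroscopic atrophy is measurable as cortical thinning. This
package implements the full surface-based analysis chain used to compare cMD
and cortical thickness between patient groups in multi-center studies, and a
synthetic phantom generator that makes every stage testable against known
ground truth. This vignette explains the models, the tunable parameters and
their defaults, what the phantoms do and do not emulate, and the numerical
choices made where the design was genuinely open.

## The processing model

**Tensor fit.** Each voxel's diffusion-weighted signal is modeled as
$S(\mathbf{g}, b) = S_0 \exp(-b\,\mathbf{g}^\top D\,\mathbf{g})$ and fitted by
ordinary least squares on $\ln S$ (`fit_tensor_loglinear()`), the default
behaviour of the standard command-line tensor fitters. The log-linear model is
exact on noiseless single-tensor data, which gives the package a machine-
precision round-trip test (forward simulation followed by fitting recovers the
tensor to ~1e-15 relative error). Non-positive signals, which can arise under
Rician noise at strong attenuation, are clamped to $10^{-6} S_0$ and flagged;
fitted tensors that fail the Sylvester positive-definiteness test are flagged
but their trace is still used for MD — no eigenvalue clipping is applied, so
MD remains an unbiased linear functional of the fit.

**Ribbon midpoint sampling.** MD is read out at the midpoint between
corresponding white and pial vertices, $m_v = (w_v + p_v)/2$, by trilinear
interpolation (`ribbon_midpoints()`, `sample_volume_at_points()`). Sampling at
the mid-thickness point minimizes partial-volume contamination from white
matter below and CSF above. Points outside the volume, or whose 8-voxel
interpolation stencil touches an invalid voxel, become *missing* — values are
never extrapolated, and missingness propagates (it is excluded from smoothing
weights and handled listwise per vertex in the statistics). An optional 4×4
affine maps surface coordinates into the diffusion frame; rigid co-registration
itself is out of scope and inputs are assumed co-registered.

An open design point: the midpoint can be defined by casting along the surface
normal or by pairing corresponding vertices. With meshes that share vertex
correspondence (always true here, and effectively true for white/pial pairs
produced by surface reconstruction) the two coincide; the corresponding-vertex
definition is implemented because it is exact on the phantom and deterministic.

**Cortical thickness** is the Euclidean distance between corresponding white
and pial vertices. Surface reconstruction itself (segmentation, spherical
registration to a template) is out of scope: all subjects share one mesh
topology, which stands in for template registration.

**Geodesic Gaussian smoothing.** Vertex maps are smoothed with weights
$\exp(-d^2/2\sigma^2)$, $\sigma = \mathrm{FWHM}/\sqrt{8\ln 2}$, where $d$ is
the geodesic distance computed by Dijkstra's algorithm on the weighted edge
graph. The default FWHM is 15 mm for both metrics, giving them equivalent
effective smoothing. Numerical choices: distances are shortest *edge-path*
lengths, not exact polyhedral geodesics — adequate when $\sigma$ is several
edge lengths, deterministic, and simple; the kernel is truncated at $3\sigma$
and renormalized over non-missing neighbors, so a constant map is reproduced
exactly and missing vertices neither receive nor contribute weight. Edge-path
distances slightly overestimate true geodesics, so the realized kernel width
is a few percent narrower than nominal (measured impulse-response FWHM
~14.2 mm for a requested 15 mm on a 2562-vertex sphere; the package asserts
agreement within 15%).

**Multi-site harmonization (ComBat).** MD is acquisition-sensitive, so site
effects are removed before analysis with the parametric empirical-Bayes
location/scale model: per vertex $v$, site $i$, subject $j$,
$y_{ijv} = \alpha_v + \mathbf{x}_j^\top\beta_v + \gamma_{iv} + \delta_{iv}\,\varepsilon_{ijv}$.
Site locations get a normal prior and site scales an inverse-gamma prior, with
hyperparameters estimated across vertices by method of moments and the
posterior updates iterated to a $10^{-6}$ absolute tolerance (cap 100
iterations — both conventional choices; convergence is typically reached in
well under 30 iterations). The fit/apply split allows a model to be estimated
once, serialized to JSON, and re-applied. Biological covariates (default:
group, age, sex, handedness — the variables later used in the GLMs) are
protected: the covariate-projected component is identical before and after
adjustment by construction. The implementation agrees with the reference
implementation in the `sva` package to ~1e-6 on shared inputs (a test, not a
dependency). The parametric variant was chosen over the non-parametric one
because it is the reference formulation and deterministic. Thickness is *not*
harmonized — site enters the thickness GLM as a nuisance covariate instead —
mirroring standard practice of harmonizing only the diffusion metric.

Whether smoothing should precede or follow harmonization is not dictated by
the model; the pipeline default is smooth-then-harmonize (harmonization then
sees exactly the maps that enter the GLM), and the order is configurable
(`smooth_before_harmonization`).

**Vertex-wise GLM and cluster-wise inference.** Each metric is regressed per
vertex on a group indicator (or a continuous severity/cognition predictor)
plus nuisance covariates — age, sex, handedness for MD; those plus site for
thickness. The contrast is tested with a two-sided Student $t$ on $n-p$
degrees of freedom. Cluster-forming thresholds follow the two-tier convention:
$\alpha = 0.001$ for whole-group comparisons, $\alpha = 0.05$ for subgroup and
correlation analyses. Suprathreshold vertices are split by the sign of $t$
(opposite effects never merge) and connected components under mesh-edge
adjacency form clusters whose area is the sum of member vertex areas (one
third of each incident triangle per vertex, so areas sum to the mesh area).

Family-wise error is controlled by Monte Carlo simulation: each repeat draws
independent standard-normal noise per vertex, smooths it with the analysis
kernel, re-standardizes empirically, forms clusters at the same threshold, and
records the maximum cluster area; 10,000 repeats by default (tests and the
acceptance script use 300–1,000, which the configuration permits, with a
warning, down to 100). A cluster's corrected p-value is the add-one estimator
$p_{\mathrm{FWE}} = (1 + \#\{\text{null maxima} \ge \text{area}\})/(n_{\mathrm{sims}}+1)$,
never exactly zero. Two deliberate simplifications: the null smooths white
noise with the *analysis* kernel rather than estimating residual smoothness
from the data (on phantoms the analysis kernel is the true smoothness; a
residual-FWHM estimator is a noted extension), and the null field is Gaussian
while observed statistics are Student — which makes the control slightly
conservative at small $n$ (measured any-significant-cluster rate ~0.01 at a
nominal 0.05 under a global null, 500 datasets). Whether correction is run
per hemisphere or whole-cortex in other software is moot here: the phantom is
a single closed surface and the correction covers it entirely.

**Effect sizes.** Cohen's $d$ per vertex is the standardized mean difference
on nuisance-residualized data (residualization is the default and is
configurable; the adjustment set excludes group so the group difference
survives). The **net effect size** is $|d_{\mathrm{MD}}| - |d_{\mathrm{CT}}|$,
restricted to the union of FWE-significant vertices from either metric, so
positive values mark cortex where microstructure carries the larger effect and
negative values where thinning does. Magnitudes are compared because the two
metrics move in opposite directions (MD up, thickness down) in disease.

## The phantom and cohort generator

The phantom is a sphere, not a brain: it preserves every quantity under test
(ribbon geometry, areas, mesh connectivity, geodesics) while making vertex
correspondence and region definitions trivial. The white surface is an
icosphere (default 3 subdivisions = 642 vertices, radius 50 mm); the pial
surface displaces each vertex along the exact radial normal by the local
thickness (default 2.5 mm). The tensor field is isotropic in the ribbon
(default MD 0.8e-3 mm²/s — a literature-typical cortical value, configurable
because patient cohorts' absolute levels vary), radially anisotropic white
matter inside (eigenvalues 1.7/0.3/0.3 e-3), and zero outside; DWI synthesis
adds Rician noise (Gaussian on two quadrature channels, then magnitude),
reproducible from a seed. Voxels default to 2.7 mm isotropic, the typical DWI
resolution scale.

Disease is injected with the spatial structure that motivates the method: an
**atrophy core** (geodesic cap, default radius 18 mm) with both thinning
(0.6 mm) and MD elevation (0.3e-3), a wider **MD-only halo** (default radius
60 mm) with elevation 0.2e-3 and no thinning, and an antipodal thickness-only
control cap for the net-effect-size sign. The halo is deliberately wide: the
15 mm kernel bleeds the core's thinning about one kernel width outward, and
the halo annulus must dominate that bleed ring for "MD-only" to hold at the
cluster level.

Observed maps add, per subject, a global random intercept (MD 0.02e-3,
thickness 0.05 mm — scanner/biology offsets) and independent vertex noise
(MD 0.25e-3, thickness 0.5 mm). With these defaults the injected standardized
effects on unsmoothed maps are 1.2 in the core and 0.8 in the halo; smoothing
then raises the detection SNR exactly as in the real pipeline. Patients'
effects are scaled by $1 + 0.1 (\mathrm{severity} - \overline{\mathrm{severity}})$,
so effect magnitude is strictly monotone in the severity score while the
group-mean effect stays at its nominal value; severity itself is drawn on the
0–24 sum-of-boxes scale with group-specific means, controls fixed at 0, and a
mild (global stage 0.5) subset drawn from the low end of the scale. Site
effects are injected on the MD field *before* any measurement — an additive
shift plus a multiplicative residual-variance scale per site — matching how
scanner differences arise physically and exactly matching the harmonization
model. Default cohort sizes reproduce a realistic multicenter case-control
study (52/31/32 non-fluent/semantic/logopenic patients, 5 mutation carriers,
89 controls, three sites).

The generator returns ground-truth and observed maps directly (`output =
"maps"`), or additionally pushes every subject's MD field through the full
forward model — per-subject pial surface, tensor volume, DWI synthesis —
(`output = "dwi"`) so the tensor-fitting and sampling stages can be exercised
end to end. Group-level statistics in the tests and the acceptance script run
in the map domain, with the scanner chain validated subject-level; this keeps
the validation suite within minutes on one CPU while still covering every
stage. Problem sizes used by the validation suite (642-vertex analysis mesh,
2562-vertex kernel checks, 30–60 subjects per group, 300–1,000 Monte Carlo
repeats, 500 null datasets) were chosen as the smallest at which the measured
quantities are stable.

What the phantom does **not** emulate: gyral geometry and curvature-dependent
partial voluming, tissue-boundary partial-volume mixtures (exterior voxels are
empty, not CSF-valued), susceptibility or eddy artefacts, registration error
(subjects share a mesh), or realistic spatial autocorrelation of biological
noise (vertex noise is white before smoothing). Passing tests therefore
demonstrate correctness of the algorithms under the stated models, not
robustness to every property of real data.

## Known limitations

- The per-subject global intercept is spatially constant, while the Monte
  Carlo null contains no global component. In correlation analyses at the
  lenient 0.05 forming threshold, a lucky correlation between subjects' global
  offsets and the predictor can shift the whole t-map and produce
  opposite-sign clusters that survive correction. This mirrors a genuine
  vulnerability of cluster-wise inference to global nuisance components;
  reported effect directions therefore summarize the peak significant vertex.
  Adding a global-mean covariate, or a null that models the global component,
  would be the natural extensions.
- Dijkstra edge-path geodesics bias the kernel a few percent narrow; exact
  polyhedral geodesics would remove this at significant complexity.
- The log-linear tensor fit is unweighted; at very low SNR a weighted fit or
  robust variants would reduce bias (the package asserts <2% median MD bias at
  the SNR used).
- Missingness is handled listwise per vertex with a 90% minimum-coverage rule;
  no imputation is attempted anywhere, by design.
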