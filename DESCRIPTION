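Package: cortexmd
Title: Surface-Based Cortical Mean Diffusivity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Surface-based analysis of cortical mean diffusivity (cMD) and
    cortical thickness for multi-center case-control studies. Provides
    log-linear diffusion tensor fitting, sampling of mean diffusivity at the
    midpoint of the cortical ribbon, geodesic Gaussian smoothing of vertex
    maps, empirical-Bayes (ComBat) harmonization of site effects, vertex-wise
    general linear models with Monte Carlo cluster-wise family-wise error
    correction, Cohen's d effect-size maps and net effect-size maps, together
    with a synthetic cortical phantom and multi-site cohort generator with
    known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    sva,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
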