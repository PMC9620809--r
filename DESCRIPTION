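Package: svdnet
Title: Structural Brain Network Analysis for Small Vessel Disease Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end diffusion-tensor network analysis for longitudinal
    trials in cerebral small vessel disease: synthetic tensor-field phantoms
    and simulated two-arm cohorts, log-linear diffusion tensor fitting with
    fractional anisotropy and mean diffusivity histogram metrics,
    deterministic streamline tractography (4th-order Runge-Kutta integration
    on the principal eigenvector field), inverse-length-weighted structural
    connectomes over a labelled parcellation, weighted global and local
    network efficiency, and permutational repeated-measures ANCOVA for
    group-by-time treatment effects with site stratification and
    white-matter-hyperintensity covariate adjustment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
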