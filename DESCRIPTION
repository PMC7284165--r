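Package: hippodwi
Title: Simulated Diffusion MR Microscopy of the Epileptic Mouse Hippocampus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates high angular resolution diffusion-weighted MR
    microscopy of fixed hippocampal sections in a mouse model of mesial
    temporal lobe epilepsy and reproduces the region-wise quantitative
    analysis applied to such data. Provides a parametric digital phantom of
    a hippocampal slice with five subfield regions (CA1, CA3, dentate gyrus
    granule cell layer, hilus, CA1 stratum radiatum), axial orientation
    fields, cell-density maps coupled to the diffusion parameters, and
    condition effects for control, ipsilateral and contralateral slices; a
    tensor-model HARDI signal simulator with Rician noise at controlled
    SNR; weighted least-squares diffusion tensor estimation with fractional
    anisotropy, mean diffusivity and in-plane orientation maps; spherical
    harmonic interpolation of apparent diffusion coefficient profiles to
    read off axis diffusivities; and the statistical workflow (axial
    V-tests, one-way ANOVA with Tukey post hoc contrasts, paired t-tests,
    Pearson correlations between diffusion and histology-proxy measures).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    Rcpp,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
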