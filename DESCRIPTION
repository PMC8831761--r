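Package: hemotherm
Title: Discrete Vascular-Porous Media Bioheat Modelling and Skin Perfusion Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates steady heat and blood transport in voxelised tissue using a
    discrete vascular-porous media model: stochastic vessel-tree synthesis by
    rapidly-exploring random trees, coupled one-dimensional Poiseuille network and
    Darcy porous-media blood flow, and a four-domain (artery, tissue, capillary,
    vein) steady energy solve with convective skin boundary conditions. Includes
    forward sweeps over inlet flow and ambient temperature, response-surface
    fitting, and inversion of three-phase (rest, heat, recover) skin-temperature
    traces to per-phase inlet blood flow with pattern classification, as used in
    thermal screening of peripheral vascular function.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    RNifti,
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
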