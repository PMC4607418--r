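Package: fruitmc
Title: Monte Carlo Light Transport in Layered Stone-Fruit Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates near-infrared photon migration through the layered
    skin-flesh-core structure of stone fruit (drupes) with a weighted Monte
    Carlo kernel: Henyey-Greenstein scattering, Fresnel/Snell boundary
    crossing, Russian-roulette termination, and radial/depth/angular scoring
    grids. Companion analytics cover diffusion-theory attenuation and
    penetration depth, detection-efficiency statistics for reflectance-mode
    fruit inspection (percentage of effective photons, flesh pathlength
    sensitivity), and convolution of impulse responses with a finite Gaussian
    beam. Includes scenario runners for core, skin, flesh and optical-property
    sweeps plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    broom,
    withr
Config/testthat/edition: 3
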