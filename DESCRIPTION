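Package: ionseed
Title: Monte Carlo Modelling of Cation Redistribution in Plasma-Treated Seeds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to model and evidence the migration of mobile cations toward
    the surface of seeds exposed to cold atmospheric plasma. Implements a
    canonical-ensemble Metropolis sampler for point cations confined to a
    charge-neutral two-dimensional disk and attracted by fixed negative charges
    deposited on the perimeter by the plasma sheath, with an activation barrier
    for moves between concentric equal-area cells that models hindered diffusion
    in seed tissue. Includes equal-area radial concentration profiles and
    enrichment statistics, reduction of X-ray photoelectron spectroscopy (XPS)
    gas-cluster-ion-beam depth profiles (etch-depth calibration, silicate-bound
    oxygen correction, element ratios, treated-versus-control comparison), and
    seedable synthetic-data generators for every stage of the analysis.
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
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    minpack.lm,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
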