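Package: biomesse
Title: Two-Biome Geographic State-Dependent Diversification Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether speciation, extinction, and range
    expansion rates differ between the tropical and temperate biomes on a
    dated phylogeny. Implements the two-region geographic state
    speciation-extinction (GeoSSE) likelihood with state-specific sampling
    fractions and an optional linear time dependence of the within-biome
    speciation rates, a constrained model space of 16 diversification
    scenarios with maximum-likelihood fitting, AIC ranking and nested
    likelihood-ratio tests, Bayesian slice-sampling MCMC with exponential
    priors, a dispersal-ratio robustness sweep, classification of species
    into biomes from latitudinal ranges, and an exact forward simulator of
    the GeoSSE process with incomplete-sampling thinning for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
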