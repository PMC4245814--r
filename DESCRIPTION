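Package: invasionABC
Title: Coalescent Simulation and Approximate Bayesian Computation for
    Invasion Demography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to reconstruct the demographic history of recent
    biological invasions from multi-locus haplotype sequence data.
    Provides a structured-coalescent simulator with founder events and
    exponential post-colonization growth, missing-data-aware population
    genetic summary statistics (nucleotide and haplotype diversity,
    segregating and private segregating sites, Tajima's D, AMOVA-based
    Fst with permutation tests, Mantel tests), approximate Bayesian
    computation with GLM-adjusted model choice and partial-least-squares
    parameter posteriors, calibration diagnostics (observed and Tukey
    depth P values, posterior quantile and coverage checks), and power
    analyses quantifying how much sequence data the inference of recent
    colonization histories requires.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    ape,
    geosphere,
    mixOmics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
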