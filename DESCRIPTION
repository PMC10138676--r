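Package: gemkit
Title: Constraint-Based Multistrain Metabolic Modeling and Panphenome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quality control, flux balance analysis and multistrain
    analysis of genome-scale metabolic models. Reads and writes SBML (Level 3
    with the flux-balance-constraints extension) and COBRA-style JSON models,
    audits mass and charge balance, dead-end metabolites and energy-generating
    cycles, screens carbon sources for growth, derives strain-specific models
    from a curated template using ortholog presence calls with a
    threshold-relaxation rule, gap-fills non-growing models with a
    minimum-cardinality reaction search, assembles the strain-by-carbon-source
    panphenome with universal/core/strain-specific classification and
    Manhattan-distance strain clustering, and compares predicted against
    measured fluxes with the biweight midcorrelation. Includes generators for
    synthetic toy networks, strain cohorts with planted gene losses and noisy
    flux measurements so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
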