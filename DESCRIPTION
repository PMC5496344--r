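Package: phycoflux
Title: Constraint-Based Modeling of Microalgal Growth and Storage Lipid
    Production
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for constraint-based analysis of compartmentalized
    genome-scale metabolic models of oleaginous microalgae. Reads and writes
    SBML Level 3 'fbc' models, evaluates gene-protein-reaction rules, checks
    elemental and charge balances, and runs flux balance analysis, flux
    variability analysis, blocked-reaction detection and flux coupling
    classification on top of the HiGHS linear-programming solver. Includes a
    qualitative growth/no-growth validation battery with confusion-matrix
    accuracy measures, quantitative growth-rate prediction from measured
    uptake rates, staged dynamic FBA for batch cultures with
    biomass-equation switching under nitrogen starvation, and a randomized
    pruning search for reaction-knockout sets that growth-couple the
    production of a storage lipid target. A deterministic generator of small
    compartmentalized toy models with planted ground truth supports testing
    of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    reticulate,
    stats,
    utils,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
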