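Package: nihba
Title: Growth-Coupled Strain Design by Network Interdiction and Hybrid
    Benders Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computational strain design for genome-scale metabolic models
    formulated as a network-interdiction (max-min) game: a metabolic engineer
    removes up to K reactions so that the guaranteed minimum flux towards a
    target product is maximised, without assuming the mutant grows optimally.
    The bilevel problem is reformulated to a single-level mixed-integer
    linear program via a Lagrangian penalty and LP duality, and solved by a
    hybrid Benders algorithm with Pareto-optimal cuts, local branching on
    Hamming distance and an in-search solution pool, returning many
    growth-coupled knockout designs per run.  Includes SBML-FBC and
    COBRA-JSON readers/writers, flux balance analysis, production envelopes,
    coupling classification, model reduction, carbon-number candidate
    selection, a direct-MILP baseline, an exhaustive brute-force oracle and
    TSV/JSON reporting with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    xml2,
    reticulate
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'MetabolicModel-methods.R'
    'solver.R'
    'fba.R'
    'milp.R'
    'hba.R'
    'io.R'
    'preprocess.R'
    'reporting.R'
    'toy.R'
    'zzz.R'
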