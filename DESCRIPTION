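Package: cometRepair
Title: Kinetic Modelling of Radiation-Induced DNA Damage and Repair from
    Comet-Assay Time-Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying DNA damage formation and repair after
    radiotherapy from single-cell assay time-courses. Implements a
    two-pathway compartment model with delayed processing steps and
    second-order final repair, integrated as a system of delay
    differential equations by a fixed-step method of steps; an
    evolutionary parameter search with gradient refinement that maps
    median percent-DNA-in-tail time-courses from the alkaline comet
    assay onto kinetic rate constants and delay times; descriptive
    statistics for comet tail intensities and gamma-H2AX focus counts
    (medians, interquartile ranges, bootstrap confidence intervals,
    permutation tests, focus-count capping and positivity); and a
    seeded synthetic-data generator that emulates a fractionated
    radiotherapy sampling design with inter-patient and inter-fraction
    heterogeneity and contamination outliers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'assay-stats.R'
    'repair-model.R'
    'dde-engine.R'
    'synthetic-data.R'
    'fitting.R'
    'cli.R'
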