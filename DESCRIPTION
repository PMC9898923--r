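Package: mitebn
Title: Bayesian-Network Analysis of House Dust Mite Molecular Sensitization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for component-resolved house dust mite (HDM) allergy cohorts
    measured with multiplex specific-IgE panels: threshold binarization of the
    11-component Der p / Der f panel, descriptive and age-stratified
    sensitization profiling, and a discrete Bayesian-network engine for
    modelling co-sensitization (BIC-scored hill-climbing and Chow-Liu structure
    learning with an optional root-node constraint, Laplace-smoothed
    conditional probability tables, exact inference by variable elimination
    with a brute-force oracle, d-separation). A synthetic-cohort generator with
    a calibrated ground-truth network allows every pipeline stage to be
    validated end to end without access to patient-level data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
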