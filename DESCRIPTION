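Package: chometab
Title: Regulated Kinetic-Metabolic Modelling of CHO Batch Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in silico platform for Chinese hamster ovary (CHO) cell batch
    cultures built around a regulated kinetic-metabolic network model (35
    lumped reactions, 46 state variables) with multiplicative Michaelis-Menten
    rate laws driven by nucleotide ratios. Simulates shake-flask batch cultures
    with an induction event, calibrates maximum-rate parameters by weighted
    least squares with sensitivity-based screening and asymptotic 95%
    confidence intervals, runs one-at-a-time global and per-variable
    sensitivity sweeps, and computes the metabolic flux-ratio biomarker panel
    (lactate/glucose ratio, pyruvate branch point, TCA-entry contributions,
    ATP turnover and partitioning) used to compare producer clones and
    induction states. Includes a synthetic-experiment generator with known
    ground truth for testing calibration and comparison workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
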