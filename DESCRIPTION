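Package: kinetox
Title: In Vitro Distribution Kinetics and Dose Metrics for Repeat-Dose
    Toxicity Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Compartmental modelling of test-chemical distribution in
    well-plate cell culture assays (medium, cells, plastic) under acute,
    repeated-dose and washout exposure scenarios, with first-order abiotic
    degradation of the chemical in the medium.  Rate constants are
    calibrated to compartment measurements by quasi-Newton minimization of
    time-point-balanced relative errors, in two stages (cell-free system
    first).  Calibrated trajectories yield kinetics-derived dose metrics
    (maximum concentration and area under the amount-time curve, in medium
    and in cells), against which resazurin viability data are re-expressed
    through four-parameter logistic regression to obtain
    exposure-scenario-independent potency estimates.  Includes an exact
    piecewise matrix-exponential solver used as an internal correctness
    oracle, a synthetic-data generator emulating destructive-sampling
    kinetic and viability experiments, and an end-to-end analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    Matrix,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
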