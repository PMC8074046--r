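Package: meropta
Title: Meropenem Target Non-Attainment Risk Assessment and Model-Based
    Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts the risk that a critically ill patient on standard
    meropenem dosing (1 g, 0.5 h infusion, every 8 h) fails the 100% T>MIC
    pharmacodynamic target.  Two risk engines are provided: a linear
    regression on the double natural-log scale between Cockcroft-Gault
    creatinine clearance and the 8-h meropenem concentration, with risk
    derived from classic linear-model prediction theory, and a
    two-compartment population pharmacokinetic model with renal-function,
    weight and albumin covariates evaluated by Monte-Carlo simulation.
    Risk can be assessed from a known MIC, from a pathogen's MIC frequency
    distribution via cumulative fraction of response (CFR), or from a
    user-chosen breakpoint.  A two-step evaluation framework quantifies
    prediction error against therapeutic drug monitoring data and
    agreement between the two engines with Lin's concordance correlation
    coefficient.  Includes a calibrated synthetic cohort and TDM data
    generator for testing and simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr
Config/testthat/edition: 3
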