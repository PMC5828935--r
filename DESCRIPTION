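Package: uadyn
Title: Semi-Mechanistic Exposure-Response Modelling of Uric Acid Disposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for semi-mechanistic exposure-response modelling of uric
    acid disposition in humans. Serum and urine uric acid dynamics are
    described by a turnover model with parallel intestinal clearance and
    renal elimination (glomerular filtration scaled by a fractional
    excretion coefficient). Saturable Emax-type drug-effect models link
    plasma concentrations of xanthine oxidase inhibitors to inhibition of
    the uric acid production rate, and of uricosuric reabsorption
    inhibitors to increases in fractional excretion. The package provides
    steady-state and time-course simulation, maximum-likelihood parameter
    estimation from multi-group trial data with a combined
    additive-proportional residual error model, model qualification
    procedures for renally impaired and hyperuricemic cohorts, seeded
    synthetic Phase-I and Phase-III style data generators, and
    steady-state treatment-planning nomograms for combination therapy
    dose selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    withr
Config/testthat/edition: 3
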