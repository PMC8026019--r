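Package: mfpbpk
Title: Whole-Body Physiologically Based Pharmacokinetic Modelling of Metformin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, simulates and fits whole-body physiologically based
    pharmacokinetic (PBPK) models of metformin in mouse (20 compartments) and
    human (21 compartments). Organs are connected by arterial and venous plasma
    flow; the small intestine and kidney are permeability-limited sub-models
    with Michaelis-Menten transporter kinetics (OCT/PMAT uptake, OCT1 efflux,
    OCT2/MATE renal secretion on top of glomerular filtration). Supports
    single- and multi-dose oral and intravenous regimens with event-based
    dosing, non-compartmental summaries (AUC, Cmax, Tmax, terminal half-life,
    steady-state metrics), mouse-to-human scale-up via absorption and
    elimination coefficients, multi-experiment parameter estimation with
    multistart least squares, tissue-proportion scenario analysis, and a
    synthetic concentration-time data generator with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
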