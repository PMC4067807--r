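Package: breathpk
Title: Pharmacokinetic Modelling of Exhaled Drug Concentrations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking exhaled drug concentrations measured breath-by-breath
    (for example propofol monitored by ion mobility spectrometry) to the plasma
    concentrations predicted by a weight-scaled Marsh three-compartment model under
    target-controlled infusion (TCI). Implements two observation models that collapse
    the plasma/breath hysteresis loop: an added lung compartment driven by a per-minute
    difference equation with rate constants k1L and kL1, and a first-order plasma-breath
    equilibration model with rate constant ke0lung. Includes a zero-intercept quadratic
    calibration between breath signal and lung concentration, joint parameter estimation
    by R-squared maximizing least squares, hysteresis diagnostics, and a seeded synthetic
    breath-study generator for end-to-end parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
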