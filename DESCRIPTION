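Package: qsdyn
Title: Autoinducer-2 Quorum-Sensing Dynamics, Calibration and Interference in Escherichia coli
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and calibrates a three-variable kinetic model of
    autoinducer-2 (AI-2) mediated quorum sensing in Escherichia coli:
    Gompertz cell growth drives AI-2 synthesis, basal uptake through the
    phosphotransferase system (PTS), and positive-feedback uptake through
    the LsrACDB transporters controlled by lsr operon expression.
    Provides differential-evolution calibration against growth, AI-2
    activity and beta-galactosidase time series via a normalized
    sum-of-squares objective, profile-likelihood identifiability scans,
    weighted-bootstrap confidence intervals, a synthetic time-series
    generator for recovery experiments, and a co-culture interference
    simulator for wild-type and LuxS-knockout strains including
    capacity-fraction and pre-culture sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
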