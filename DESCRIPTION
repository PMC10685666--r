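Package: vbesim
Title: Oral Pharmacokinetic Simulation and Virtual Bioequivalence Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mechanistic oral pharmacokinetic prediction of
    immediate-release products and in-silico bioequivalence assessment.
    Implements linear mammillary compartmental disposition models (one to
    three compartments) with analytic and numerical solvers, compartmental
    model fitting and AIC-based selection from oral concentration-time data,
    a compartmental absorption-and-transit (ACAT-style) gastrointestinal
    model driven by in-vitro dissolution profiles, non-compartmental
    analysis (Cmax, Tmax, AUC, terminal slope), dissolution profile tools
    (Weibull fitting, f2 similarity, rapid-dissolution classification),
    parameter sensitivity analysis, and repeated virtual two-period
    crossover trials with geometric-mean-ratio 90 percent confidence
    interval bioequivalence judgment. Includes seeded synthetic-data
    generators for dissolution and plasma datasets so the whole pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
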