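Package: dualenrich
Title: Dual-Enrichment Modeling and Gas Kinetics for N2O-Respiring Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing dual (alternating-substrate) serial
    enrichment cultures of N2O-respiring bacteria. Implements a three-species
    Lotka-Volterra logistic competition model for serial batch transfers between
    soil and digestate, with regime mapping of generalist enrichment outcomes;
    headspace gas-kinetics calculus (dilution and leakage correction, cumulative
    production, two-population exponential rate decomposition, transfer survival
    fractions, electron flows, nitrogen mass balance, and the N2O emission index
    I_N2O); OTU-level community statistics (rarefaction, ddPCR-scaled absolute
    abundances, per-enrichment ratios R_i, niche classification, Ward clade
    clustering, SIMPER); and a synthetic-data generator with planted ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    minpack.lm,
    jsonlite,
    vegan,
    S4Vectors,
    SummarizedExperiment
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
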