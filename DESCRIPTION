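Package: tilcea
Title: Early Cost-Effectiveness Model of TIL Therapy Versus Ipilimumab in
    Advanced Melanoma
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decision-analytic cost-effectiveness model comparing tumor
    infiltrating lymphocyte (TIL) therapy with ipilimumab for second-line
    treatment of advanced melanoma from the Dutch health-care perspective.
    Provides fixed-effect logit-scale pooling of single-arm survival
    proportions, a three-state Markov cohort model (stable disease,
    progressive disease, death) run over annual cycles with differential
    discounting of costs and effects, probabilistic sensitivity analysis
    with moment-matched Beta and Gamma parameter distributions,
    cost-effectiveness acceptability curves and net monetary benefit,
    expected value of perfect information, tornado-style one-way
    sensitivity analysis, scenario analysis, and threshold-price search.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
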