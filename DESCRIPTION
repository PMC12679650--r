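Package: maickit
Title: Matching-Adjusted Indirect Comparison of Two Randomized Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for anchored and unanchored matching-adjusted indirect
    comparison (MAIC) of a trial with individual patient data against a trial
    reported only as aggregates. Implements method-of-moments propensity
    weighting with effective-sample-size diagnostics, weighted mixed-effects
    models for repeated measures with an unstructured residual covariance,
    weighted Cox proportional-hazards fits for composite kidney endpoints,
    Bucher and conjugate Bayesian fixed-effects indirect comparisons, and a
    calibrated synthetic two-trial generator for longitudinal eGFR and
    proteinuria outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nlme
Config/testthat/edition: 3
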