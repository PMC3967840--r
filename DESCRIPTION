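Package: deprev
Title: Cost-Effectiveness Modelling of Depression Prevention in Primary Care
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Decision-analytic model of depression prevention strategies for
    general-practice attendees: a screening decision tree (risk-algorithm
    stratification by sensitivity and specificity) feeding a quarterly
    three-state Markov cohort model (no major depression, depressed,
    recovered) over a 12-month horizon. Computes costs and quality-adjusted
    life years from an NHS perspective, net monetary benefit, probabilistic
    sensitivity analysis with beta/gamma/log-normal parameter uncertainty,
    cost-effectiveness acceptability curves, and the standard scenario
    analyses (risk-score threshold variants, alternative treatment-effect
    odds ratios, maximum affordable programme cost by effectiveness,
    universal-uptake sweep, half-cycle correction).
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    graphics,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
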