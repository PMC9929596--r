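Package: fatop
Title: Operating-Point Analysis of Body-Fat Regulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the operating-point model of body-fat regulation, in
    which steady-state fat and food intake sit at the intersection of two
    experimentally measurable curves: the diet line (steady-state fat at a
    fixed, controlled food intake) and the appetite line (ad-libitum daily
    intake at a given fat level), coupled through leptin feedback.  The
    package provides closed-form and numeric solutions of the operating
    point in the leptin-sensitive and satiety-capped regimes, ODE
    simulation of fat-leptin-intake dynamics with classification of intake
    overshoots and undershoots, a rule engine predicting whether an
    intervention moves fat and intake coherently or opposingly, pipelines
    that fit diet and appetite lines to normalized controlled-feeding
    experiments and fit the quadratic leptin-fat relation in population
    data, local log-sensitivity analysis of the steady state, diet and
    appetite lines derived from two earlier leptin-based models, and a
    synthetic-data generator for controlled-feeding time series and
    leptin-fat population scatters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
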