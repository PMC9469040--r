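Package: diffscale
Title: Maximum-Likelihood Difference Scaling with Nonlinear Scaling Functions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing suprathreshold difference judgments collected
    with the method of triads. Fits a possibly nonlinear difference-scaling
    function (a monotone cubic Hermite spline or a discrete monotone mapping)
    by multi-restart maximum likelihood under a Thurstonian (Case V) choice
    model, tests for nonadditivity of perceived differences (diminishing or
    increasing returns) with a regression on triad accuracy, and provides a
    Monte Carlo simulation harness for method-of-triads designs, including
    goodness-of-fit diagnostics (RMSE to a known ground truth, AIC, response
    prediction accuracy, k-fold cross-validation, residual diagnostics).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
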