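Package: postselsim
Title: Simulation Toolkit for Post-Model-Selection Inference in Penalized Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Monte-Carlo machinery for studying how data-driven variable
    selection distorts downstream inference in linear and logistic
    (case-control) regression.  Generates sparse-truth datasets under
    configurable predictor correlation structures and error laws, fits a
    panel of penalized selection estimators (LASSO, LAR, elastic net,
    relaxed LASSO, one-step SCAD, combined L1/L2 penalized GLMs, and
    forward-stepwise ridge logistic regression) with fivefold
    cross-validated tuning, constructs normal-approximation confidence
    intervals either directly from the penalized estimates (adaptive) or
    from an unpenalized refit on the selected support (oracle refit), and
    aggregates false-positive/false-negative selection rates and three
    coverage criteria across seeded replicates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
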