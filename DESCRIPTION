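Package: semsgd
Title: Simultaneous Equation Models as Masked Linear Networks Trained by
    Stochastic Gradient Descent
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of linear simultaneous-equation models (SEM) by viewing
    the system as a masked single-layer linear network whose free weights are the
    structural coefficients, trained with mini-batch stochastic gradient descent
    under element-wise gradient clipping. Ships a from-scratch two-stage
    least-squares (2SLS) baseline, per-equation OLS, structural/reduced-form
    algebra with order-condition identification checks, a fully seeded synthetic
    SEM generator (uniform coefficients, Gaussian designs and noise), and a
    Monte-Carlo benchmark harness that compares estimators by validation
    mean-squared error across a grid of model sizes, noise levels and sample
    sizes. All user-facing functions take data frames and return tibbles; fitted
    objects support broom-style tidy() and glance() and ggplot2 autoplot().
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
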