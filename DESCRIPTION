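Package: wdrolad
Title: Wasserstein Distributionally Robust Absolute-Deviation Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Robust linear regression by distributionally robust optimization
    over a Wasserstein ball of distributions on the joint predictor-response
    space. The worst-case expected absolute loss admits exact convex
    reformulations: a linear program when the transport metric is induced by
    the l1 or l-infinity norm, and a second-order-cone form for the l2 or a
    general M-weighted norm, in each case an empirical absolute-deviation loss
    plus the Wasserstein radius times the dual norm of the extended
    coefficient vector (-beta, 1). The package provides these estimators
    together with classical baselines (OLS, ridge, LASSO, elastic net, and
    IRLS M-estimation with Huber, Talwar and Fair weights), a synthetic
    contaminated-regression benchmark, validation-based tuning by median
    absolute deviation, generalization-bound and sample-size calculators,
    residual-based outlier detection with ROC/AUC evaluation, and tidy
    accessors plus ggplot2 visualisations for all result types.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    boot,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
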