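Package: cvaudit
Title: Resubstitution Bias and Cross-Validated Accuracy Audits for
    Small-Sample Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Monte-Carlo machinery and audit tools for quantifying how badly
    estimating a classifier's accuracy on its own training data
    ("resubstitution", the training-set optimisation practice common in
    verbal credibility assessment research) inflates reported accuracy in
    small samples, and how leave-one-out cross-validation removes the
    inflation.  Provides a synthetic-data generator with a prescribed
    point-biserial predictor-outcome correlation, a two-class pooled-
    covariance linear discriminant classifier, four accuracy-estimation
    schemes (resubstitution, leave-one-out, stratified k-fold, independent
    test set), factorial simulation harnesses producing accuracy and
    accuracy-difference curves, a points-of-stability corridor scan for
    sample-size planning, and an exact-binomial accuracy audit for coded
    statement tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
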