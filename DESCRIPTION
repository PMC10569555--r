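Package: holdoutbss
Title: Best-Subset Regression with Events-per-Variable Rules and
    Repeated Hold-Out Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exhaustive best-subset selection for linear, binary-logistic
    and multinomial-logistic prediction models, regularised by
    events-per-variable (EPV) rules, R-squared/shrinkage sample-size
    criteria and expert constraints (forced terms, model-weight and
    correlation bounds), with candidate models ranked by their average
    predictive power (absolute/relative error, accuracy or AUROC) over
    many random hold-out splits.  Includes quadratic and cubic
    interaction expansion of numeric designs, comparator selection
    strategies (univariate-significance, stepwise-forward and
    L1-penalised models evaluated on identical splits), an overfitting
    measure, a seeded synthetic-data generator and a command-line front
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    glmnet,
    jsonlite,
    parallel
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC
Config/testthat/edition: 3
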