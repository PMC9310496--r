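Package: efsemble
Title: Evolutionary Feature Selection for Weighted-Vote Classifier Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint per-classifier feature selection and classifier weighting by
    a genetic algorithm, for imbalanced clinical classification tables. A
    two-layer chromosome couples a weight vector over heterogeneous base
    learners (k-nearest neighbours, support vector machine, linear discriminant
    analysis, naive Bayes, decision tree) with a binary per-learner feature
    selection matrix; candidate solutions are scored under stratified k-fold
    cross-validation by a weighted combination of classification error, false
    acceptance rate and false rejection rate. Includes preprocessing recipes
    for clinical cohort tables (derived age, body-mass index, lymph-node
    ratio, strict volume-threshold labelling, minority-class replication),
    repeat-run feature-impact ranking, and a seeded synthetic lymphedema-like
    cohort generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    nnet,
    purrr,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
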