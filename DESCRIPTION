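Package: rpgp
Title: Random-Projection Feature Construction with Genetic-Programming
    Classification for High-Dimensional Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies high-dimensional gene-expression profiles (d features,
    d >> N samples) by first constructing a small number of features with a
    seeded random projection whose columns have unit length, then evolving a
    tree-based genetic-programming classifier over the arithmetic primitives
    {+, -, x, protected /} whose fitness is the standardized Matthews
    correlation coefficient (1 + MCC)/2.  Includes the full evaluation
    harness (stratified 10-fold cross-validation, repeated seeded runs,
    decision-tree, naive-Bayes, k-nearest-neighbour, support-vector-machine
    and random-forest baselines), delimited and ARFF readers for expression
    matrices, and a seeded generator of microarray-like synthetic data with a
    planted class signal so the whole pipeline can be exercised end to end
    without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    class,
    e1071,
    foreign,
    randomForest,
    rpart,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
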