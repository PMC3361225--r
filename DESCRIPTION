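Package: poolsim
Title: Virtual Pooling Designs and Classifier Performance in Omics Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation framework to quantify how pooling biological
    samples affects supervised classification in high-dimensional omics
    studies. Generates two-class mock omics datasets (Gaussian
    class-conditional features with uniformly drawn marker effect sizes
    and additive technical noise), pools training samples on the natural
    scale (log of the mean of exponentiated values plus fresh technical
    error), ranks features by the two-sample Student t-statistic, tunes
    six classifiers (linear and radial kernel support vector machines,
    random forest, k-nearest neighbours, L2-penalized logistic
    regression, and nearest shrunken centroids) by internal
    cross-validation, and estimates misclassification rates on
    individual-sample test sets across Monte-Carlo replications, with
    Wilcoxon rank-sum comparisons between designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
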