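Package: nmrules
Title: Exhaustive Supervised Rule Mining for Discretized Multi-Source
    Biomedical Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mines one- and two-dimensional subgroup rules from discretized
    multi-source biomedical tables (for example quantile-binned 1H-NMR urine
    metabolomic buckets together with clinical variables), scores them with a
    one-proportion z statistic and a modality-size support threshold, removes
    dominated rules, and uses the surviving rules as binary features in
    L2-penalized logistic classifiers of a binary clinical outcome such as
    chronic kidney disease stage. Includes the spectral preprocessing chain
    (equidistant ppm bucketing, region exclusion, integral normalization,
    pareto scaling, quantile discretization), a repeated stratified holdout
    evaluation protocol with inner cross-validation, permutation significance
    testing and Jaccard feature-stability, a synthetic data generator with
    planted marginal and interaction effects, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
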