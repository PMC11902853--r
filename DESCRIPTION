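Package: gcnet
Title: Directed Brain Network Construction, Graph Analysis and Classification
    from ROI Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds directed (Granger-causal) and undirected (Pearson)
    functional connectivity networks from region-of-interest time series,
    binarizes them by proportional thresholding with global-cost-efficiency
    maximization, extracts global and nodal graph-theoretic features,
    identifies hub regions from connection-strength and out-degree rankings,
    and classifies subject groups with a Mann-Whitney-filtered support vector
    machine. Includes a seeded multivariate-autoregressive cohort simulator
    with planted group effects so every stage can be validated against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    e1071,
    pROC,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
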