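Package: pwsc
Title: Polynomial Weight-Adjusted Sparse Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Clustering of sparse non-negative feature-by-sample matrices,
    such as binary somatic-mutation tables or microbial abundance profiles,
    in which raw Euclidean distances between samples are dominated by the
    overwhelming majority of zero entries.  Feature rows are reweighted by a
    user-chosen polynomial of their observation frequency, the reweighted
    samples are clustered by Ward agglomerative linkage, and the number of
    clusters is chosen by Monti consensus resampling with the proportion of
    ambiguous clustering (PAC) and CDF delta-area statistics.  Includes
    partition-quality metrics (entropy, Calinski-Harabasz index), per-cluster
    biomarker occurrence reports, a planted-cluster synthetic data generator,
    delimited-text and MatrixMarket input/output, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
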