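Package: lccaselect
Title: Latent Class Cluster Analysis with Extended Cluster-Number Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits latent class cluster models (finite mixtures of products of
    multinomial distributions) to categorical survey-style data by EM with
    random restarts, and implements an extended strategy for selecting the
    number of clusters that combines model fit (BIC, ICL, elbow heuristic),
    cluster separation (average silhouette width on a simple-matching
    dissimilarity), and stability of partitions (bootstrap adjusted Rand
    index and Jaccard coefficient). Includes pre-clustering diagnostics
    (multilevel ICC screening, missingness exploration, chained
    tree-ensemble imputation, category frequency reports), a seeded
    generator for ordinal clustered data with controllable separation,
    post-selection diagnostics (population shares, per-item discriminative
    power, item-probability, silhouette and principal-component figures),
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    ggplot2,
    patchwork,
    jsonlite,
    ranger
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    optparse
Config/testthat/edition: 3
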