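Package: bimodr
Title: Detection of Bimodally Expressed Transcripts by Cluster Branch Heights
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Screens normalized, log-scale expression matrices for transcripts
    whose abundance splits into two distinct populations of individuals.
    For each transcript the individuals are clustered by Ward agglomerative
    hierarchical clustering of their one-dimensional expression values; the
    maximum dendrogram branch height remaining after trimming merges driven
    by single extreme individuals is used as a bimodality statistic, and a
    parametric bootstrap from a fitted normal null yields an empirical
    p-value per transcript. Includes cross-condition intersection of hits,
    optional Benjamini-Hochberg adjustment, diagnostics plots, synthetic
    matrix generators with planted bimodal and outlier transcripts for
    calibration and power studies, and genotype-by-expression-class
    segregation analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    optparse,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
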