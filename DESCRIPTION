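Package: goannopt
Title: Optimizing Gene Set Annotations with Ontology Structure and Expression Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extends a binary gene-to-GO-term annotation matrix into a
    probabilistic one by a downward random walk with restart over the
    Gene Ontology directed acyclic graph, with edge weights given by Lin
    semantic similarity, and then filters annotations that are
    inconsistent with the cluster structure of gene expression data by
    consensus over a range of k-means cluster counts and bootstrap
    resamples of samples. Includes readers and writers for OBO, GAF,
    GMT and TSV matrix formats, evaluation metrics (Kendall's
    coefficient of concordance, rank-based ROC/AUC,
    Benjamini-Hochberg adjustment, a rank-sum competitive enrichment
    test), and a synthetic-data generator with planted inconsistent
    annotations for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    pROC
Config/testthat/edition: 3
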