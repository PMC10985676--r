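Package: CTEC
Title: Cross-Tabulation Ensemble Clustering for Single-Cell RNA-Seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Consensus clustering for single-cell RNA-seq by iterative
    cross-tabulation rectification. Given two or more cluster-label
    assignments over the same cells plus a low-dimensional embedding,
    CTEC matches cluster labels through a contingency table and corrects
    one labeling from another with either a distribution-based rule
    (coefficient-of-variation threshold with an annealed schedule) or an
    outlier-based rule (copula-based outlier detection on the embedding),
    iterating column- and row-wise passes to a consensus labeling. A
    progressive scheduler ensembles more than two methods by discarding
    the worst input under the Calinski-Harabasz score and repeatedly
    merging the most dissimilar pair by adjusted Rand index. Includes
    from-scratch ARI, NMI and Calinski-Harabasz metrics, a synthetic
    benchmark generator with controlled clustering errors, and readers
    for label tables and dense or MatrixMarket feature inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, tools, Matrix, jsonlite, BiocGenerics
Suggests: testthat (>= 3.0.0), e1071, mclust
Config/testthat/edition: 3
biocViews: SingleCell, Clustering, Transcriptomics, RNASeq
RoxygenNote: 7.3.3
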