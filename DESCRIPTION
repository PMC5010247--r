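Package: mutseg
Title: Mutation-Position Segmentation of Tumour Expression Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links the position of somatic mutations within a driver gene to
    downstream gene-expression changes in tumour cohorts. Patients carrying a
    single mutation in the driver are ordered by ranked mutation position and
    each gene's ranked expression is segmented by circular binary segmentation
    with permutation-based split significance; genes with at least one
    segmentation breakpoint are called response genes. Also provides in-silico
    translation of coding indels to classify frameshifts as C-terminal
    truncations or extensions, group-level differential statistics (median
    fold change, Wilcoxon rank-sum), cross-cohort sign concordance, and
    Kaplan-Meier/log-rank survival comparison, together with a synthetic
    cohort simulator with full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    SummarizedExperiment,
    S4Vectors,
    survival,
    jsonlite,
    data.table
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
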