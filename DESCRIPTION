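Package: earlyReprog
Title: Early OSKM Reprogramming Time-Course Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the early phase of OSKM-mediated fibroblast
    reprogramming profiled on bead arrays: detection-call present/absent
    filtering, empirical-Bayes moderated-t differential expression versus the
    donor fibroblast with regulation-profile encoding, derivation of
    pluripotency- and fibroblast-associated gene sets and their activation
    time course, fuzzy c-means clustering of regulated transcript profiles,
    a seed-based EMT-suppression signature (genome-wide co-expression
    ranking, leave-out recovery test, Spearman suppression statistic and
    binomial over-representation test), and a source-to-sink interaction
    network analysis with a weighted shortest-path betweenness node score.
    A seeded synthetic-data module emulates the study design so every stage
    is testable against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: GeneExpression, Microarray, DifferentialExpression, Clustering,
    Network, TimeCourse
RoxygenNote: 7.3.3
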