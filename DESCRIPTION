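Package: fatlas
Title: Mapping When Stem-Cell Fate Diversity Emerges from Single-Cell
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for locating the stage at which stem-cell fate
    diversity arises in planarian neoblasts and their post-mitotic (G0)
    progenitors. Provides quality control and gating of droplet scRNA-seq
    UMI matrices (isoform collapsing, UMI-bound filters, log-normalization,
    marker-gene gating), detection of fate-specific transcription-factor
    modules by pairwise Pearson correlation and UPGMA clustering,
    ensemble-coexpression classification of progenitor fate with precision
    estimates, Ratkowsky-Lance index state counting over repeated seeded
    k-means, stage-to-stage correlation-shift and cluster-matching
    analyses, rule-based transcription-factor cataloging from HMMER and
    BLAST tabular output, and a seeded synthetic-data generator that
    emulates the statistical structure of the study design so every stage
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    igraph,
    mclust,
    methods,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
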