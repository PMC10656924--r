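Package: recolonizr
Title: Deterministic Microbial Succession Analysis for Host Recolonization
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for bacterial recolonization time series of
    germfree hosts and inert control substrates: community ordination and
    permutation statistics (PERMANOVA, ANOSIM, PCoA, Chao1) on ecological
    dissimilarities, core-taxon succession filtering with early/late
    colonizer classification, greedy 97% identity clustering of 16S
    amplicon sequence variants with genome assignment, abundance-weighted
    projection of genome-derived metabolic pathway repertoires onto 16S
    community profiles, and repeated shadow-feature random-forest selection
    of stage-associated pathways with subsystem scoring. Includes a
    synthetic recolonization experiment generator with planted ground truth
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    ranger,
    stats,
    tools,
    utils,
    vegan
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
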