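Package: chromodyn
Title: Temporal Chromatin Accessibility and Gene Expression Module Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrated temporal analysis of chromatin accessibility
    (ATAC-seq peak counts) and gene expression (RNA-seq counts) across
    developmental stages: TMM normalization and negative-binomial
    differential calling, seeded k-means clustering of stage trajectories
    into six temporal modules with silhouette validation, peak-to-gene
    assignment and Fisher module-module association, position weight
    matrix scanning with exact p-values and module motif enrichment,
    transcription-factor footprint aggregation, motif-supported TF-target
    network construction with a cross-species similarity score, and
    discovery of lineage-accelerated conserved noncoding regions.
    Includes a synthetic-data generator with planted ground truth so
    every stage of the pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    IRanges,
    ape
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    cluster,
    mclust,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
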