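Package: splicescape
Title: Alternative Splicing Events and Inter-Individual Splicing Variation
    from RNA-Seq Splice Junctions
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-alignment analysis of alternative splicing in
    multi-individual bulk RNA-seq. Loads gene annotation from GFF3, derives
    introns and collapsed exon models, filters splice-junction evidence by
    read support and anchor overhang, detects and classifies four
    alternative-splicing event types (intron retention, alternative 5' and
    3' splice sites, exon skipping), quantifies the long-isoform
    (inclusion) frequency of each event from junction read counts, computes
    FPKM expression summaries, and measures inter-individual splicing
    variation with Spearman correlation, average-linkage clustering, and
    per-event pairwise Fisher exact tests under Benjamini-Hochberg FDR
    control. Ships a seeded synthetic-data generator that emits the exact
    file formats the pipeline consumes together with ground truth, so every
    stage is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
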