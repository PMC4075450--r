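Package: cisgrammar
Title: Cistrome-Transcriptome Integration for Hormone-Responsive
    Transcription Factor Networks
Version: 0.1.0
Authors@R:
    person("Plant Regulatory Genomics", "Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for integrative analysis of transcription-factor binding
    (ChIP-seq peaks) and hormone-responsive gene expression in plants:
    peak-to-gene target calling by promoter/body/downstream windows,
    cis-element grammar statistics (motif enrichment against genomic
    background, AuxRE/E-box co-occurrence classes, element spacing,
    association with hormone-activated genes, binding-score comparisons),
    multi-factor target-set overlap with hypergeometric expectations,
    peak-to-peak distance distributions, ChIP-qPCR and RT-qPCR ratio
    arithmetic, threshold-based differential expression calling, and
    cross-pathway dependence statistics (fold-change correlation,
    sign-pattern co-regulation, response retention). Includes a fully
    deterministic synthetic-data generator (toy genome, planted motifs at
    configurable spacing, Venn-structured multi-factor target sets,
    negative-binomial expression with planted effect retention and
    fold-change correlation) so that every stage is verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
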