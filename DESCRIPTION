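Package: plasmidtx
Title: Transcriptome Profiling of Bacterial Plasmids: Promoters,
    Terminators, Codon Usage and Carriage Effects
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrated toolkit for transcriptome analysis of bacterial
    plasmids and megaplasmids. Quantifies gene expression from count tables
    (RPKM, TPM) and assigns transcription tiers by an expression floor plus
    quartile rule; maps transcript boundaries (TSS/TTS) from strand-specific
    per-base coverage and assembles transcriptional units with 5'/3' UTR
    lengths; fits a bipartite -35/spacer/-10 promoter model by constrained
    expectation-maximisation and scans degenerate IUPAC regulatory motifs;
    detects GC-rich hairpins and classifies transcriptional terminators
    (rho-independent, stem-loop, convergent); computes codon-usage indices
    (RSCU, CAI, CBI, GC3, hydropathy, aromaticity) and relates plasmid tRNA
    carriage to host codon adaptation; and calls plasmid-carriage
    differential expression with k-means/SSE clustering, fold-change,
    p-value and FDR filtering plus functional-class-scoring enrichment.
    Includes a fully seeded synthetic-data generator that plants promoters,
    terminators, regulon motifs and differential expression with a recorded
    ground truth, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    SummarizedExperiment,
    limma,
    edgeR,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
biocViews: Transcriptomics, GeneExpression, DifferentialExpression,
    MotifDiscovery, Coverage, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
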