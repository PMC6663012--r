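Package: ProteoRhythm
Title: Circadian Label-Free Proteomics and Proteogenomic Genome Annotation
    Refinement
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for untargeted label-free quantitative proteomics of
    staggered time-course designs: charge and top-N spectrum filtering,
    median normalization, peptide-sum protein quantitation with an inverse
    hyperbolic sine transform, target-decoy false discovery rates,
    time-of-day detectability profiling, one-way ANOVA prefiltering, and a
    from-scratch JTK_CYCLE rhythmicity test with an exact permutation null.
    A proteogenomics workflow identifies peptides confidently matched in a
    multi-species proteome collection but absent from a target predicted
    proteome, collapses them into containment groups, summarizes taxonomic
    support, and classifies each group against the genome into annotation
    error categories (overlapping gene models, uncalled genes, single
    mismatch or 1-nt frameshift "wobbly" hits, assembly gaps). A synthetic
    data module generates time-course abundance data with known rhythmic
    truth, proteome collections, peptide-spectrum match tables, and toy
    genomes with planted annotation defects, so every stage is testable
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    Biostrings,
    SummarizedExperiment,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    GenomicRanges
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
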