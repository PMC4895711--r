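Package: txlandscape
Title: Bacterial Primary Transcriptome and Translatome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping bacterial transcription start sites (TSS) from
    differential RNA-seq (TEX+/TEX-) 5'-end profiles, classifying TSSs against
    a genome annotation (primary, secondary, internal, antisense, intergenic),
    quantifying 5'-UTR lengths and leaderless mRNAs, scanning -10/-35 promoter
    consensus elements and spacer geometry, and measuring translation
    efficiency and translational buffering from matched RNA-seq and
    ribosome-profiling count matrices across growth phases. Includes a
    synthetic-data generator with planted ground truth (TSS positions,
    fold-changes, buffering slope, operon stoichiometry) so every stage of the
    pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
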