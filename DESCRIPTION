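Package: lncscape
Title: Strand-Specific Identification and Characterization of Plant Long Non-Coding RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A strand-aware pipeline for identifying long non-coding RNAs
    (lncRNAs) from assembled transcript models, classifying them into long
    intergenic non-coding RNAs (lincRNAs) and long non-coding natural
    antisense transcripts (lncNATs), and characterizing them: molecular
    features (length, exon number, splicing ratio, GC content, SNP density,
    splice-site base composition), transposable-element origination
    (gene-body and exonic TE overlap, Class I/II composition, TE-derived
    promoters and transcription-factor sites within them), PhastCons
    conservation profiles with a sliding-window conserved-patch statistic,
    cross-species homology matrices, Jensen-Shannon tissue-specificity
    scoring, and candidate selection for co-expression network analysis.
    Includes a deterministic synthetic-data generator that emits every
    input format with planted ground truth, so the full pipeline is
    testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
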