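Package: methcons
Title: Cross-Species Conservation Analysis of Tissue-Specific DNA Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for comparative epigenomics of tissue-specific DNA
    methylation across three species. Calls tissue-specific hypomethylated
    differentially methylated regions (tsDMRs) on 500-bp genomic windows from
    per-CpG methylation tracks, maps them to orthologous regions in other
    genomes through UCSC chain files with coverage and span filters, builds
    three-way orthologous regions by reconciling direct and composed liftover
    paths, classifies each ortholog as epigenetically conserved (EC) or
    non-conserved (ENC) from categorical methylation states, relates
    epigenetic to genetic conservation via conserved-element overlap and
    conservation-score binning, computes feature-matched enrichment
    statistics (TSS distance, genomic features, histone peak summits, signal
    profiles), scans IUPAC consensus and PWM motifs and classifies
    cross-species binding-site turnover, and generates a fully specified
    synthetic three-species benchmark with a ground-truth table for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    jsonlite
Config/testthat/edition: 3
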