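Package: isocouple
Title: Coupling of Transcription Start Sites, End Sites and Exons from
    Long-Read RNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects statistically coupled combinations of transcription
    start sites (TSS), transcription end sites (TES) and exon junctions
    within single full-length cDNA reads from long-read RNA sequencing.
    Builds a 5'-3' isoform database from a GTF annotation by clustering
    transcript ends, optionally augmented with external promoter and 3'
    end databases; assigns genome-aligned long reads to (TSS, TES)
    cluster pairs keeping only full-length reads; tests per-gene TSS x
    TES contingency tables for independence with a Monte-Carlo
    chi-squared test and Benjamini-Hochberg correction, reporting
    Pearson residuals and promoter-dominance summaries; and corrects
    noisy long-read splice junctions against a reference junction set
    (annotation plus short-read STAR junctions) to test couplings
    between exon inclusion and TSS or TES usage. A synthetic-data
    generator with known coupling structure supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    data.table,
    GenomicAlignments,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    methods,
    rlang,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
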