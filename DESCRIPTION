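Package: smucompare
Title: Evaluating De Novo Transcriptome Assemblies Across Sequencing Technologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing de novo transcript sets produced by short-read
    (HiSeq/MiSeq-class) and long-read (Iso-Seq-class) sequencing against a draft
    genome. Implements single-mapping-unit (SMU) analysis with per-technology
    coverage-improvement and nonredundant splice-variant statistics, splice
    variant classification (length variants, intron retention, exon skipping),
    H1/H2/H3 full-length completeness scoring from protein hit tables,
    genome mapping rates at coverage/identity thresholds, assembly length and
    GC statistics, hypergeometric and Monte Carlo rarefaction curves,
    library-specificity counting, and MFEI-based miRNA precursor triage.
    A synthetic-data generator emulates a multi-scaffold genome, multi-isoform
    gene models and technology-specific transcript sets with truth alignments
    so that every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
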