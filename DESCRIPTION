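Package: dgetag
Title: Digital Gene Expression Tag Profiling from NlaIII/MmeI Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for SAGE-style digital gene expression (DGE)
    tag profiling. Extracts CATG-anchored 17 nt virtual tags from a
    transcript reference (the in-silico analogue of NlaIII/MmeI digestion),
    cleans raw tag libraries (N-containing tags, adaptor-derived tags,
    copy number below 2), assigns unique clean tags to transcripts allowing
    at most one mismatch, quantifies expression as tags per million and
    RPKM, calls differential expression between libraries with the exact
    Audic-Claverie tag-count test, classifies cross-species developmental
    expression patterns as similar (S) or different (D), computes Venn-style
    set overlaps of expressed tags or genes, and produces per-library
    summary tables with mapping ratios. A synthetic-data module simulates
    reference transcriptomes and error-bearing tag libraries with known
    ground truth so every stage is testable without sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
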