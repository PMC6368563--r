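Package: regsnpscan
Title: Allele-Aware Motif Scanning and Regulatory SNP Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies transcription-factor binding-disrupting SNPs by
    allele-aware position weight matrix scanning with exact match p-values
    (dynamic programming over the discretized log-odds score distribution
    under a zero-order background) inside ChIP-Seq peak-summit windows, and
    provides the downstream statistics used in regulatory-variant studies:
    per-locus consensus prioritization over heterogeneous annotation scores,
    MAF-matched resampling enrichment tests, exact binomial allele-specific
    expression tests, multi-dataset eQTL target-gene tiering, LD partner
    screening, developmental-stage expression comparisons, and a
    synthetic-data generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
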