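Package: promobind
Title: Promoter Binding Landscapes for Paired Transcription-Factor ChIP Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of transcription-factor binding in promoter regions from
    ChIP-on-chip style data: TSS-anchored binding profiles (mean signal and
    percent-bound per 50 bp bin), classification of promoters by single versus
    multiple binding of one factor and co-binding with a second factor,
    hypergeometric co-binding enrichment, observed-versus-randomized peak-peak
    distance tests with Fisher's exact test, motif-density scans against
    soft-masked genome sequence with iterative k-mer enrichment, and
    integration of binding classes with gene expression. Includes a synthetic
    data generator that emulates a bimodal upstream/downstream binding factor
    (OTX2-like) co-occurring with a TSS-centered factor (MYC-like), so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
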