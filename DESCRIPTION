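Package: gliopanel
Title: Paired Tumor-Normal DNA Panel Analysis for CNS Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for targeted DNA panel sequencing of central
    nervous system tumors from per-locus tumor and matched-normal read
    counts. Implements paired small-variant calling with a Fisher-exact
    somatic test and false-positive filtering, loss-of-heterozygosity
    detection from heterozygous-SNP allele-ratio shifts, copy-number
    calling against a per-sample size-sorted segment baseline, a rule
    engine producing integrated CNS-tumor diagnoses (including 1p/19q
    codeletion, molecular glioblastoma features, medulloblastoma molecular
    subgroups and meningioma risk flags) with therapy annotations and an
    oncoprint-style alteration matrix, plus a purity-aware tumor-normal
    read-count simulator and coverage/performance QC utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
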