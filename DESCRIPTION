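Package: niptpool
Title: Pooled Variant Calling and Allele-Frequency Estimation from
    Simulated NIPT Cell-Free DNA Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates ultra-low-coverage maternal-plasma cell-free DNA
    sequencing cohorts (non-invasive prenatal testing, NIPT) with known
    truth, applies per-sample alignment filtering (mapping quality,
    overlapping-read deduplication), pools reads across samples, calls
    single-nucleotide variants with a binomial sequencing-error model,
    estimates population allele frequencies from pooled read counts, and
    validates the call set: panel partitioning, common-SNP sensitivity,
    allele-frequency correlation, transition/transversion ratios,
    sex-chromosome depth accounting, Hardy-Weinberg carrier frequencies,
    and principal component analysis of genotypes simulated from
    estimated allele frequencies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    yaml,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    optparse
Config/testthat/edition: 3
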