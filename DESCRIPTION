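Package: ampliscreen
Title: Amplicon Editing Quantification and Off-Target Screening for
    Staggered-Cut CRISPR Nucleases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies CRISPR editing efficiency from deep amplicon
    sequencing using a read-pattern classification rule (left-normalized
    indel patterns, minimum indel size and per-pattern read-count
    thresholds, homopolymer masking), enumerates genome-wide candidate
    off-target sites for a spacer under a 5'-PAM rule with mismatch and
    bulge budgets, and screens whole-genome variant call sets for
    off-target edits through a hard-filter cascade (two-caller
    intersection, QD/FS/MQ/SOR thresholds, background subtraction,
    coverage and allele-balance filters, simple-repeat masking).
    Includes synthetic-data generators emulating staggered-cut repair
    deletions and paired call sets, so the whole pipeline is testable
    without external data, and the closed-form binomial power of the
    allele-balance filter for heterozygote detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    yaml,
    withr,
    optparse
Config/testthat/edition: 3
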