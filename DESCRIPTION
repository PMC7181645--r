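Package: indelstrand
Title: Transcriptional Strand Asymmetry of Indels at Repeat Tracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures transcriptional strand asymmetry of small insertions and
    deletions (indels) at mononucleotide and dinucleotide repeat tracts.
    Builds a strand-oriented repeat-tract atlas from a reference genome and a
    gene annotation, orients tracts to the template or non-template strand of
    each overlapping gene, intersects normalized indel calls with the atlas,
    and computes background-corrected strand-bias statistics with gene-level
    bootstrap dispersion, exact binomial tests, MSI/MSS enrichment ratios and
    down-sampling z-scores. Analyses can be stratified by gene expression
    tier, tract length, replication timing quantile and leading/lagging
    replication orientation. A synthetic-data generator with a ground-truth
    manifest provides planted-parameter cohorts for calibration and power
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    rtracklayer,
    dplyr,
    tibble,
    tidyr,
    car,
    jsonlite,
    withr,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
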