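Package: svbk
Title: Case-Control Analysis of Structural Variants, Copy-Number Variants,
    and Short Tandem Repeats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A downstream analysis toolkit for whole-genome case-control
    studies of structural variants (SVs), copy-number variants (CNVs), and
    short tandem repeats (STRs). Provides cross-sample call-set filtering
    and interval merging, squared-reciprocal-overlap SV identity matching,
    mutated-allele-frequency summaries with PCA stratification checks,
    5 Mb-window and chromosome-terminal CNV burden scans, regionally
    stratified association testing combined by sample-size-weighted
    Stouffer Z meta-analysis, a binomial genotype-likelihood caller for
    biallelic STRs from long-read support counts with cross-platform
    concordance scoring, penetrance-modification analysis, statistical
    power calculations, and cell-type expression specificity enrichment
    with fold-change dosage-sensitivity scores. A synthetic-cohort
    generator with planted effects makes the full pipeline testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
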