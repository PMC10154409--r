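Package: subteloscan
Title: Telomere-Proximity Analyses of Transposable Elements, Mutations and
    Chromatin Contacts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy analysis toolkit for telomere-proximity genomics in
    telomerase-deficient cells: subtelomeric enrichment testing of
    differentially expressed transposable-element (TE) instances against a
    genomic-density baseline (exact hypergeometric test with a multi-threshold
    scan), baseline-subtracted genomic-category spectra of SNVs/indels and
    single-base substitution classes, k-mer classification of structural-variant
    insertion sequences against a TE consensus library, telomeric (TTAGGG)n
    read quantification and H3K9me3 peak classification with a flanking-gene
    metagene, and arm-resolved Hi-C subtelomere interaction profiling from
    valid-pair files. Ships a synthetic-data generator that plants recoverable
    ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
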