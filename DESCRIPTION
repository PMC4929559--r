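Package: rhizolink
Title: Linking Root-Exudate Metabolite Absence Patterns to Nonsense Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for associating natural variation in LC/MS root-exudate
    metabolite profiles of Arabidopsis thaliana accessions with genome sequence
    variation. Implements blank filtering of feature matrices with Welch
    heteroscedastic tests and Benjamini-Hochberg correction, half-minimum
    imputation, surrogate-variable batch correction, average-linkage clustering
    on Pearson correlation distances with multiscale-bootstrap approximately
    unbiased (AU) cluster support, pairwise mismatch distances from variant
    tables restricted to coding sequence, premature-stop-codon calling for
    enzyme genes, isotope-aware monoisotopic feature annotation, and exact
    matching of metabolite absence patterns against stop-codon patterns.
    Includes a synthetic-data generator with planted gene-to-metabolite links
    so the whole workflow is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    ape
Config/testthat/edition: 3
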