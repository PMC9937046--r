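Package: imprintase
Title: Reciprocal-Cross Allele-Specific Expression Analysis for
    Imprinted Gene Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects genomic imprinting from reciprocal-cross RNA-seq
    allele counts: informative-SNP discovery and filtering with
    parent-of-origin allele assignment, allelic-ratio quantification and
    gene-level aggregation, flipped-pattern classification of maternally
    and paternally expressed genes with a cis-eQTL guard, flagging of
    candidates subject to imprinted X-chromosome inactivation, promoter
    bisulfite-clone methylation calling with differentially-methylated-
    region classification, and extrapolation of the genome-wide imprinted
    gene count from informative-SNP coverage. Includes a seeded synthetic
    generator that emulates a two-stock reciprocal cross so every stage
    can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    stats,
    utils,
    rlang,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
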