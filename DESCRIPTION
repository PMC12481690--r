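Package: svdimorph
Title: Structural-Variant Callset Merging, Dimorphic Mobile-Element
    Annotation and Admixture-Aware Selection Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-calling analysis of structural-variant (SV) callsets from
    long-read, short-read and assembly-based discovery in canine genomes:
    callset-level filtering and normalisation, breakpoint-proximity merging
    with representative selection and between-modality concordance, local
    alignment of SV allele sequences against a repeat consensus library to
    classify dimorphic SINE and LINE-1 elements by reciprocal overlap, a
    six-frame ORF-intactness scan for full-length LINE-1s with poly(A) and
    target-site-duplication detection, and an admixture-component
    allele-frequency likelihood-ratio scan for loci under selection.  A
    synthetic-data generator produces every pipeline input with a known
    truth table so the whole workflow is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
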