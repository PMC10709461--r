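Package: periflow
Title: Interspecific Gene Flow Across Recombination Categories of the Genome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test whether pericentromeric recombination suppression
    restricts interspecific gene flow, as proposed for the 'large X effect'
    in hybridising Silene campions. Computes per-gene polymorphism and
    divergence statistics (nucleotide diversity, Tajima's D, Fst, Dxy and
    Kelly's ZnS) over codon-aware site classes, builds joint site-frequency
    spectra for gene categories defined by chromosome and local recombination
    rate, fits five isolation-with-migration demographic models with
    heterogeneous migration by Poisson composite likelihood over a
    Monte-Carlo structured-coalescent expected spectrum, compares categories
    with rank-based tests and compact letter displays, and tabulates
    interspecific gene-expression divergence from FPKM matrices. A
    structured-coalescent simulator generates complete synthetic datasets
    with the assumed statistical structure so the whole pipeline runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    tools,
    Rcpp,
    Biostrings,
    vcfR,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    ape,
    ggplot2
Config/testthat/edition: 3
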