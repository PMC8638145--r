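Package: prolaminr
Title: Prolamin Gene Family Discovery, Annotation and Expression Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for genome-wide characterization of cereal prolamin
    (gliadin and glutenin) gene families: nucleotide homology scanning by
    seed-chain-extend with an E-value style filter, full-length locus
    extraction, rule-based subfamily classification (alpha-, gamma-,
    omega-, delta-gliadins, LMW and x/y-type HMW glutenin subunits),
    pseudogene calling from ORF integrity, molecular weight and
    isoelectric point computation, tandem-duplication clustering under
    distance/coverage/identity rules with transitive extension,
    micro-collinearity chaining with inversion detection, celiac-disease
    epitope profiling of functional proteins, and TPM-based developmental
    expression profiling.  Ships a synthetic genome generator that plants
    prolamin-like gene families with known truth labels so every pipeline
    stage can be validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    methods,
    Rcpp,
    rtracklayer,
    stats,
    stringi,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
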