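Package: wrkyr
Title: Annotation and Evolutionary Classification of WRKY Transcription
    Factor Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and curates WRKY DNA-binding domains in protein
    sequences, assigns them to the evolutionary groups of the plant WRKY
    family (I, IIa-IIe, III and the non-plant types) using diagnostic
    signature variants, zinc-finger spacing grammars and intron positions,
    classifies chimeric resistance-protein/WRKY genes into the RW1-RW8
    architecture families, and builds distance-based phylogenies
    (Poisson-corrected p-distances, pairwise deletion, site-coverage
    filtering, neighbor joining with bootstrap support).  A seeded
    synthetic-data generator with machine-readable truth tables makes the
    whole pipeline testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
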