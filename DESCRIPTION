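Package: domex
Title: Structure and Function Exchange Between Membrane-Protein
    Extramembrane Domains and Soluble Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and characterising shared domains between
    the extramembrane regions of membrane proteins and water-soluble
    proteins. Implements Kabsch superposition, TM-score with the standard
    d0 length scaling, an iterative dynamic-programming structural aligner,
    the similarity screening pipeline (RMSD / aligned-length / TM-score
    thresholds, transmembrane-overlap and disconnected-loop removal,
    topology side assignment, 30 percent identity redundancy reduction,
    domain-coverage annotation), functional-site shell conservation scoring
    with PAM-250, membrane-distance geometry with a Mann-Whitney U group
    comparison, secondary structure element alignment (SSEA) with
    resampling-based cutoff training, and a synthetic-structure generator
    that emulates every input the pipeline assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
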