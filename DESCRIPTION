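Package: ctdlab
Title: Repeat Instability Analysis for the RNA Polymerase II CTD Coding Region
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying length instability of the degenerate 21-bp tandem
    repeat that encodes the RNA polymerase II C-terminal domain (CTD) in budding
    yeast. Decomposes a CTD coding region into repeat units and aligns repeat
    architectures across strains at the unit level (distinguishing whole-unit
    gains and losses from single-nucleotide polymorphisms); computes strand
    composition, G-C/A-T sliding-window skew profiles and QGRS-style
    G-quadruplex motif calls; estimates mutation rates from Luria-Delbruck
    fluctuation assays with the Ma-Sandri-Sarkar maximum-likelihood estimator
    and Stewart confidence intervals; classifies suppressor colonies into
    expansion, contraction, recombination and other events and calls deletion
    junctions with microhomology; and generates seeded synthetic data with
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
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
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
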