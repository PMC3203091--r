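Package: hybcoal
Title: Detecting Hybridization in the Presence of Incomplete Lineage Sorting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the hybridization proportion and speciation times on a
    fixed hybrid species tree from multi-locus rooted gene-tree topologies
    with multiple sampled individuals per species, under a mixture of
    multispecies-coalescent gene-tree distributions over the two parental
    trees. Provides the coalescent gene-tree topology probability kernel
    (coalescent-history enumeration with Tavare's lineage-count
    probabilities), maximum-likelihood estimation by cyclic bounded Brent
    optimization, a likelihood-ratio test of no hybridization against a
    50:50 mixture of a point mass at zero and chi-squared with one degree
    of freedom, an ITERATE mode that cycles the hybrid assignment over the
    ingroup species, and a full simulation pipeline (coalescent gene trees,
    Jukes-Cantor sequences, maximum-likelihood gene-tree re-estimation,
    power study).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phangorn,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
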