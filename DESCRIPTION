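Package: plastomics
Title: Comparative Chloroplast Genome Analysis and Divergence Hotspot Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated plastid (chloroplast)
    genomes: detection of the quadripartite LSC/IRb/SSC/IRa architecture and
    its junction gene context, repeat detection and classification
    (dispersed, tandem, palindromic, gene-similarity), extraction and
    alignment of homologous regions (exons, introns, intergenic spacers),
    divergence statistics (parsimony-informative character content,
    uncorrected p-distances with complete deletion), maximum-parsimony
    phylogenetics (Fitch scoring, exhaustive, branch-and-bound and heuristic
    searches, nonparametric bootstrap, consistency and retention indices),
    the incongruence length difference (partition homogeneity) test, and an
    end-to-end divergence-hotspot scan that ranks candidate phylogenetic
    markers. A plastome evolution simulator with a ground-truth manifest
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Rcpp,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    withr,
    optparse,
    phangorn,
    testthat (>= 3.0.0)
LinkingTo:
    Rcpp
Config/testthat/edition: 3
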