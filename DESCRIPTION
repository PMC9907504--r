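Package: lichenbgc
Title: Mycobiont Genome Isolation and Biosynthetic Gene Cluster Family
    Analysis for Lichen Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for comparative metagenomics of
    lichen-forming fungi. Isolates the mycobiont (fungal symbiont) contig
    set from a lichen metagenome by combining tetranucleotide/coverage
    Gaussian-mixture binning with taxonomy-aware anchor selection, AT-rich
    tail merging and contaminant filtering; groups biosynthetic gene
    clusters (BGCs) into families with a composite distance over domain
    content, sequence identity and domain order, clustered by affinity
    propagation; computes comparative statistics of family
    presence-absence profiles (Sorensen beta-diversity partition into
    turnover and nestedness, Jaccard dissimilarity, principal coordinates
    analysis, Mantel and PERMANOVA permutation tests, partial F-tests);
    and screens clusters for the conserved four-gene anthraquinone
    architecture (ABC-transporter, metallo-beta-lactamase thioesterase,
    non-reducing polyketide synthase, EthD). Ships seeded simulators for
    metagenomes, BGC panels and presence-absence matrices evolved along
    trees, so every stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    mclust,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
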