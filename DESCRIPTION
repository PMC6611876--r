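Package: polysv
Title: Structural Variation, Introgression and Population Genetics for
    Polyploid Genome Comparisons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-genome-alignment-based discovery of structural
    rearrangements (inversions, translocations), presence-absence
    variation and homoeologous introgression between pairs of plant
    genome assemblies, together with the downstream population-genetic
    analyses that characterise large inversions in an accession panel:
    breakpoint genotyping from mate-pair mappings, windowed nucleotide
    diversity, Weir-Cockerham F_ST, haplotype diversity, private-SNP
    accounting, neighbor-joining grouping and recombination-rate
    windows, plus Kimura two-parameter dating of transposable-element
    copies.  A synthetic-genome generator produces cultivar pairs,
    ancestor genomes, accession panels, mate pairs and genetic maps
    with known truth so every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    methods,
    ape,
    dplyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
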