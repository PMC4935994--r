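Package: satkit
Title: Iterative Satellite-DNA Discovery, Classification and Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers satellite-DNA families from low-coverage paired-end
    reads by iterative cluster-filter-recluster cycles: reads are
    quality-filtered, clustered on a similarity graph, satellite candidates
    are selected by cluster density and shape, consensus monomers are derived
    from tandem-structured contigs, and reads matching known repeats are
    subtracted before each further round so that progressively rarer families
    surface. Consensus monomers are classified into variants, families and
    superfamilies by identity thresholds, named in order of decreasing
    abundance, and related by minimum spanning trees. Abundance (genome
    proportion) and Kimura 2-parameter divergence are estimated by aligning
    reads or assembly contigs against concatenated-monomer references,
    yielding repeat landscapes and per-contig repeat statistics.
    Dinucleotide-preserving genome shuffling estimates the chance occurrence
    of short monomers, a simulator generates satellite-bearing genomes and
    paired reads with known truth, and satellitome-level summary statistics
    are computed from annotation tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    stringr,
    readr,
    rlang,
    ggplot2,
    generics,
    igraph,
    stats,
    utils,
    Biostrings,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse,
    jsonlite
Config/testthat/edition: 3
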