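Package: repeatscape
Title: Transposable-Element Discovery and Genome Community Analysis from
    Unassembled Short Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Graph-based identification and quantification of repetitive
    element families directly from unassembled whole-genome shotgun reads.
    Paired-end reads are quality- and complexity-filtered, subsampled, and
    compared all-against-all with a k-mer seeded banded Smith-Waterman
    aligner; the resulting weighted similarity graph is partitioned with
    the Louvain modularity algorithm and clusters are merged through
    mate-pair links and annotated against a repeat consensus library to
    yield per-family genomic proportions with replicate-based uncertainty.
    Downstream layers provide read-depth genome-size estimation from a
    transcript reference, rank-abundance model fitting (brokenstick, niche
    preemption, lognormal, Zipf, Zipf-Mandelbrot) with BIC model selection,
    Shannon diversity statistics, and phylogenetic comparative tests
    (Blomberg's K with contrast-permutation significance, phylogenetically
    independent contrasts, and phylogenetic generalized least squares).
    Includes generators for synthetic repeat-bearing genomes, paired-end
    reads, and Brownian-motion traits with ground-truth ledgers for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    nlme,
    picante,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
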