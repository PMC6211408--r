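Package: damidomains
Title: DamID-Seq Normalization, HMM Domain Calling and Domain Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of DamID-seq experiments that map
    protein-genome interactions (nuclear lamin, HP1a, Polycomb) in binned
    read counts. Converts replicate Dam and Dam-POI count tables into
    merged, reads-per-million normalized log2(Dam-POI/Dam) profiles with
    optional cross-tissue quantile normalization; segments profiles into
    protein-bound domains with a two- or three-state Gaussian hidden
    Markov model that respects missing-bin gaps; and quantifies domain
    coverage, pairwise overlap, conservation across cell types,
    chromosome-level shifts, gene-expression association, metagene
    profiles around transcription start sites, and transposable-element
    proximity, with permutation nulls built by length-preserving
    shuffling within chromosome arms. A synthetic-data generator plants
    domain architectures, negative-binomial counts, expression tables
    and TE insertions with known truth so every stage is testable
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    limma,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
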