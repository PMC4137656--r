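Package: orthodiverge
Title: Pairwise Comparative Genomics of Closely Related Bacterial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing two closely related annotated bacterial
    genomes, built around the divergence structure typical of endosymbionts
    such as Wolbachia: reciprocal-best-hit ortholog mapping over an internal
    seed-and-extend nucleotide aligner, codon-level divergence by the
    Nei-Gojobori (1986) pathway-counting method with Jukes-Cantor correction
    (per-gene and concatenated genome-wide Ka/Ks), synonymous molecular-clock
    divergence dating, threshold screens for divergent and positively
    selected genes, outgroup polarization of derived alleles, prophage-region
    delineation tolerant of mobile-element interruptions and scaffold breaks,
    pseudogene fragmentation detection, genome-reduction reporting, and
    gene-order synteny blocks. Includes a codon-aware genome-pair evolver
    that simulates descent from a common ancestor with known ground truth
    (substitutions with controlled Ka/Ks, in-frame indels, prophage-region
    deletion, premature-stop fragmentation, repeat-gene insertion) for
    end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
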