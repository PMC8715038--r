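Package: isforge
Title: Insertion-Sequence Transposon Mutagenesis Toolkit for Bacterial
    Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computational toolkit around insertion-sequence (IS) based
    random transposon mutagenesis in bacteria such as Corynebacterium
    glutamicum. Implements a comparative-genomics "genome healing" designer
    that finds IS-free syntenous regions in donor genomes and emits
    scarless deletion constructs with homology arms; a sequence-level model
    of a Bxb1 serine-integrase genetic switch (attB x attP to attL/attR
    promoter inversion and plasmid integration) plus a degenerate attB site
    scanner; a junction caller that turns long-read alignments of
    marker-anchored enrichment libraries into deduplicated insertion sites
    with strand and replichore assignment; target-site preference analysis
    (position frequency/information matrices, sequence logos, central
    tetranucleotide frequencies); and a fully seeded synthetic-data
    generator (genome, PWM-biased insertions with target-site duplication,
    fragmented marker-anchored reads, naive seeded aligner) so the whole
    pipeline runs and is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    Rcpp,
    ggplot2,
    stats,
    utils,
    grDevices,
    graphics,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
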