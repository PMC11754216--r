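Package: vdjloci
Title: Annotation and Analysis of T Cell Receptor V(D)J Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering and characterizing T cell receptor (TCR)
    gene loci in genomic sequence. Detects and scores recombination signal
    sequences (RSS) with a trainable position-frequency log-odds model,
    assembles heptamer/spacer/nonamer hits into typed V, D, J and C gene
    segment calls under the 12/23 rule, clusters V segments into families by
    pairwise percent nucleotide identity, maps cDNA transcripts to germline
    segments to classify V(D)J rearrangement completeness and productivity,
    detects transmembrane regions by hydropathy and classifies chains by
    their conserved Arg/Lys charge asymmetry, builds neighbor-joining trees
    with bootstrap support, and compares conserved synteny around loci. A
    ground-truthed synthetic locus and repertoire generator makes every
    stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    yaml,
    withr,
    Rcpp,
    methods,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
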