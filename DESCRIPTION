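Package: TRkit
Title: Germline Annotation, Expressed-Repertoire Analysis and Simulation of
    T Cell Receptor Loci
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the computational characterization of T cell receptor
    (TR) loci in non-model mammals. Discovers and classifies germline V, D, J
    and C genes in genomic locus sequences using position-specific profiles
    and recombination-signal (RS) detection, applies IMGT-style unique
    numbering and F/ORF/P functionality rules, and assembles cassette- or
    cluster-organized locus maps. Profiles RS heptamer/nonamer conservation
    as position weight matrices, processes 5'RACE amplicon reads into AIRR
    rearrangement tables with junction extraction and V/J usage and pairing
    statistics, and builds neighbor-joining V-REGION phylogenies with
    bootstrap support. A bundled V(D)J locus and repertoire simulator with
    full ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    ape,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
biocViews: Annotation, Alignment, Sequencing, ImmunoOncology, Phylogenetics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
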