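Package: myxocol
Title: Contamination-Aware Transcriptome Filtering and Minicollagen Mining
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for cleaning de novo transcriptome assemblies that are
    co-contaminated by a host and a closely related co-infecting species,
    using identity-weighted BLAST hit-coverage scoring of contigs, plus a
    suite for mining and characterising myxozoan minicollagen genes:
    cysteine-rich domain (CRD) motif scanning, Gly-X-Y collagen repeat
    counting, linker composition classification, heuristic Ncol typing,
    intron localisation from genomic/transcript pairs, and gene-cluster
    intergenic geometry.  Includes a deterministic synthetic-data
    generator, assembly QC statistics (N50, GC), alignment preparation
    (polyproline excision), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
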