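Package: lgtscan
Title: Detection and Characterization of Lateral Gene Transfers in
    Root-Knot Nematode Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for detecting candidate lateral
    gene transfers (LGT) of non-metazoan origin in the genomes of
    root-knot nematodes (Meloidogyne incognita and M. hapla) and for
    characterizing their fate after acquisition. Implements
    ortholog-group restriction and representative selection, a
    taxonomy-aware BLAST top-hit vote, a contamination filter, a gene-tree
    topology scan for receiver/donor/external clade patterns with graded
    phylogenetic support, species-overlap duplication inference and
    duplication-timing classification, genomic-context statistics
    (LGT-gene clustering, transposable-element density in flanking
    windows, scaffold-end positioning, GC content and codon usage),
    Pfam-to-GO functional profiling with GO-slim projection, screening
    against mobile-genetic-element proteins, and headline enumeration
    reports. A seeded synthetic-data generator produces a fully
    consistent miniature study with ground-truth labels so every stage is
    testable without external downloads.
License: MIT
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
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    GenomeInfoDb,
    jsonlite,
    phangorn,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
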