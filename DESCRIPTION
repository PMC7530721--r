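Package: cpuorf
Title: Genome-Wide Identification of Conserved Peptide Upstream Open Reading Frames
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exhaustive extraction of upstream open reading frames (uORFs) from
    annotated 5'-UTRs of animal genomes and identification of conserved peptide
    uORFs (CPuORFs). Implements the full search pipeline: transcript model
    assembly from genome FASTA and Ensembl-dialect GFF3, exhaustive uORF
    scanning, uORF-mORF fusion-ratio filtering against RefSeq-like transcript
    collections, permissive translated homology search with downstream main-ORF
    orthology confirmation, contaminant removal, conservation across at least
    two taxonomic orders, pairwise Ka/Ks purifying-selection testing with an
    empirical permutation null and Benjamini-Hochberg correction, taxonomic
    range classification over the standard metazoan category ladder, and
    classification of CPuORFs into numbered homology-group families. Includes a
    deterministic synthetic-fixture generator so the whole pipeline is testable
    without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
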