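Package: blastmine
Title: Population-Scale BLAST Search Orchestration, Motif Mining and
    Sequence Curation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A modular toolkit for alignment-based genome mining across
    large collections of assemblies. Automates NCBI BLAST+ database
    creation and multi-query searching with automatic program dispatch
    (blastn, blastp, tblastn), curates hits into unified, filtered and
    strongest-match tables, mines amino-acid motifs with a wildcard
    pattern language, extracts aligned regions or whole contigs with
    genomic-context padding, and ships utilities for FASTA handling
    (sanitization, splitting, collision-free headers), assembly metrics
    (N50/L50, GC content) and GenBank/JSON metadata harvesting, plus
    percent-identity heatmaps and per-motif sequence logos. All
    functions are available from R and through a single command-line
    entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    digest,
    ggplot2,
    jsonlite,
    parallel,
    stats,
    tools,
    utils
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
SystemRequirements: NCBI BLAST+ >= 2.16 (makeblastdb, blastn, blastp,
    tblastn) on the PATH for database construction and searching.
Config/testthat/edition: 3
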