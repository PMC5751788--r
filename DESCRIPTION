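Package: dualseg
Title: Dual Segmentation for Massively Parallel Sequence Similarity Search
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Splits both a query FASTA set and a reference FASTA database
    into record-preserving chunks, enumerates the M x N grid of
    (query-chunk, database-chunk) search tasks with array-job style task
    identifiers, runs each task through a built-in seed-and-extend
    nucleotide aligner (or an external search command), corrects
    per-fragment E-values to the full database using Karlin-Altschul
    statistics and the effective number of database sequences, verifies
    and checkpoints partial results, and merges them into a single ranked
    report identical to an unsplit run. Includes a deterministic synthetic
    fixture generator, a local multi-process executor, and SGE/Slurm
    array-job script emission.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    parallel,
    optparse,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
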