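# dualseg

Dual segmentation for massively parallel sequence similarity search.

## The problem

BLAST-style searches of large query sets against large nucleotide
databases parallelize poorly with threads (one node) or MPI (one master
core, whole-database memory pressure). But the pairwise search is
embarrassingly parallel once **both** inputs are segmented: split the
query set into *M* chunks and the database into *N* chunks, and every
(query-chunk, database-chunk) pair is an independent task. An array job
of *T = M × N* tasks gives *O(T)* theoretical speed-up, each task small
enough to cache in a node's memory, and checkpointing for free — a
failed task is one result file to regenerate, not a job to restart.

The statistical catch is that an E-value computed against a database
*fragment* is too optimistic. `dualseg` corrects this natively: every
task knows the effective number of sequences and total residue count of
the *original* database and computes each hit's Expect value against the
global search space, so the merged report is identical — hit for hit,
E-value for E-value — to an unsplit run.

The package provides the full workflow for R users: record-preserving
FASTA splitting, the array-job task-grid arithmetic
`task_id = (I2 − 1)·M + I1` and its inverse, a built-in ungapped
seed-and-extend nucleotide aligner (Rcpp) so everything runs without
external software, Karlin–Altschul statistics (λ solved exactly, K from
the standard ungapped constants or a renewal-series computation,
edge-effect length adjustment), checkpoint verification with
`failed.lst` rerun manifests, result merging in BLAST tabular
(outfmt 6) dialect, a local multi-process executor, SGE/Slurm array
script emission, and a deterministic synthetic fixture generator.

## The statistics in brief

For a match/mismatch scheme with background frequencies *pᵢ*, λ is the
positive root of Σ pᵢpⱼ e^(λsᵢⱼ) = 1; bit scores are
S′ = (λS − ln K)/ln 2; and E = m′·n′·2^(−S′) over the length-adjusted
search space m′ = m − ℓ, n′ = n − N_seq·ℓ, where n and N_seq are the
**global** database residue count and effective sequence count. Raw
scores of ungapped alignments are independent of which sequences share
a fragment, so re-globalizing fragment hits reproduces the unsplit run
exactly. See the methods vignette
(`vignettes/dual-segmentation.Rmd`) for derivations and design notes.

## Worked example

```r
library(dualseg)

fx <- generate_fixture(seed = 1)          # 40 queries vs 200 subjects, ~100 kb
write_fixture(fx, "fixture")

res <- run_pipeline("fixture/query.fasta", "fixture/db.fasta", "work",
                    query_chunk_bytes = 2200, db_chunk_bytes = 33000)
res$plan
#> Dual-segmentation job plan: 4 x 3 = 12 task(s), 1 thread(s)/task, 12 total slot(s)
#> Effective number of sequences in the database is 200; total residue count is 89,273.

head(res$hits[, c("query_id", "subject_id", "percent_identity",
                  "align_length", "evalue", "bit_score")])
#>    query_id  subject_id percent_identity align_length    evalue bit_score
#> 1 query_002 subject_147           100.00           36 9.337e-15     69.90
#> 2 query_008 subject_154            97.67           43 4.861e-17     77.59
#> 3 query_009 subject_077            95.83           48 3.302e-18     81.44
#> 4 query_010 subject_169           100.00           41 1.479e-17     79.52
#> 5 query_012 subject_076           100.00           16 5.246e-03     31.45
#> 6 query_014 subject_007            97.56           41 7.025e-16     73.75
```

The fixture plants 40-bp homologies (98% identity) in half the queries;
the merged report recovers each as its query's best hit. `query_002`'s
hit, for instance, spans query positions 16–51 against
`subject_147` 163–198 at 100% identity — 36 matched residues, raw score
36, bit score 69.9, and E ≈ 9.3 × 10⁻¹⁵ *against the full 89 kb
database*, not the ~30 kb fragment the task actually searched. The
12 partial files merge to the same bytes as an unsplit (1 × 1) run:

```r
unsplit <- run_pipeline("fixture/query.fasta", "fixture/db.fasta", "work1",
                        query_chunk_bytes = 1e9, db_chunk_bytes = 1e9)
identical(readLines(res$merged_path), readLines(unsplit$merged_path))
#> [1] TRUE
```

For a cluster, emit the equivalent array script instead of running
locally (any backend command template works; `{dbseqnum}` carries the
global sequence count to each task):

```r
cat(emit_array_script(res$plan, "sge",
    "blastn -query {query} -db {db} -out {out} -outfmt 6 -dbseqnum {dbseqnum}"))
#> #!/bin/sh
#> #$ -cwd
#> ...
#> #$ -t 1-12
#> TASK_ID=$SGE_TASK_ID
#> M=4
#> I1=$(( (TASK_ID - 1) % M + 1 ))
#> I2=$(( (TASK_ID - 1) / M + 1 ))
#> ...
```

After a partially failed run, `verify_run()` writes a `failed.lst` of
task IDs (e.g. missing `results.1_2` and `results.151_1` in a 152 × 27
grid map to tasks 153 and 151), `run_local(..., task_filter = ...)`
reruns exactly those, and the restored merge is byte-identical.

A command-line interface wraps the same functions
(`inst/cli/dualseg`): subcommands `fixture`, `split`, `stats`, `plan`,
`run`, `verify`, `rerun`, `merge`, `script`.

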