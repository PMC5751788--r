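---
title: "Dual segmentation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual segmentation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualseg)
```

## The problem and the method

A BLAST-style similarity search compares every query sequence against
every database sequence. Two partial parallelization strategies are well
known: slicing the query set (each slice searched against the whole
database) and splitting the database (the whole query set searched
against each fragment). *Dual segmentation* combines them: split the
query set into $M$ chunks and the database into $N$ chunks, and search
every one of the $M \times N$ chunk pairs as an independent task. On a
cluster this maps naturally onto an *array job* — $T = M \times N$ tasks
distinguished only by an integer task ID — giving $O(T)$ theoretical
speed-up, bounded-memory tasks (each pair can be sized to fit a node's
cache), and free checkpointing: each task's result file is independently
verifiable and re-creatable, so a failure costs one task, not the job.

The workflow is five steps, each backed by a module of this package:

1. record the statistics of the original database — its effective number
   of sequences and total residue count (`compute_db_stats()`);
2. split query and database into record-preserving chunks of bounded
   byte size (`split_fasta()`);
3. enumerate the unique chunk pairs (`build_plan()`);
4. run the $M \times N$ tasks (`run_local()` locally, or
   `emit_array_script()` for an SGE/Slurm array job), each task writing
   `results.<i1>_<i2>`;
5. verify and merge the partial results into one ranked report
   (`verify_run()`, `merge_results()`).

## Task indexing

A scheduler hands each task one integer. The package uses the
column-major convention

$$\text{task\_id} = (I_2 - 1)\,M + I_1,$$

where $I_1 \in 1..M$ indexes the query chunk (varying fastest) and
$I_2 \in 1..N$ the database chunk. `pair_from_task_id()` is the exact
inverse, and the emitted array scripts decode the scheduler's task-ID
variable with the same arithmetic (`I1 = (t-1) mod M + 1`,
`I2 = (t-1) div M + 1`), so `results.<i1>_<i2>` names are stable across
runs, schedulers, and the local executor. All indices are 1-based,
mirroring scheduler task-ID semantics; the package never exposes a
0-based task index. Task order is never rearranged (e.g. for load
balancing), because the `result_name` ↔ `task_id` correspondence is what
makes checkpoint verification trivial.

## E-value statistics under database fragmentation

The statistical content of the method is that a task searching a
database *fragment* must report E-values as if it had searched the whole
database; otherwise merged results depend on how the database was split.
For an ungapped match/mismatch scoring scheme with background base
frequencies $p_i$, the Karlin–Altschul theory gives

- $\lambda$: the unique positive root of
  $\sum_{ij} p_i p_j e^{\lambda s_{ij}} = 1$ (`solve_lambda()`, bracketed
  root-finding, residual $\le 10^{-9}$);
- $H = \lambda \sum_{ij} q_{ij} s_{ij}$ with target frequencies
  $q_{ij} = p_i p_j e^{\lambda s_{ij}}$;
- $K$: for the common nucleotide pairs (+1/−2 … +1/−5 under uniform
  frequencies) a bundled table of the standard ungapped constants; for
  any other viable scheme the renewal-series computation
  $K = d\lambda e^{-2\sigma} / \big(H(1 - e^{-\lambda d})\big)$, where
  $d$ is the lattice span of the score values and
  $\sigma = \sum_{j\ge1} \tfrac1j\big[\mathrm{E}(e^{\lambda S_j}; S_j<0)
  + \mathrm{P}(S_j \ge 0)\big]$ is summed over the exact distributions
  of $j$-step score sums (direct convolution, truncated when a term
  falls below $10^{-12}$; the terms decay geometrically because the walk
  has negative drift). The series reproduces the tabled constants to
  three decimals, which is how the table was validated.

Bit scores are $S' = (\lambda S - \ln K)/\ln 2$ and
$E = m'\,n'\,2^{-S'}$, where $m' = m - \ell$ and
$n' = n - N_{\text{seq}}\,\ell$ are the length-adjusted query and
database sizes. The length adjustment $\ell$ is the standard edge-effect
fixed point $\ell \leftarrow \ln\!\big(K(m-\ell)(n - N_{\text{seq}}
\ell)\big)/H$ from $\ell = 0$ (at most 20 iterations, stop when the
update is below 0.5, clamped so $m' \ge 1$ and
$n' \ge N_{\text{seq}}$, floored).

`globalize_hits()` applies this with the *global* database statistics —
total residue count $n$ and effective sequence count $N_{\text{seq}}$ of
the original, unsplit database — to hits found in any fragment. The
per-position raw score of an ungapped alignment does not depend on which
other sequences share the fragment, so raw scores are
partition-invariant and the globalized E-values are identical to those
of an unsplit run, which the test suite checks hit-for-hit.

Two design points were genuinely open and are resolved as follows.
First, the effective sequence count enters *both* the search-space
product and the length adjustment; applying it to only one of the two
would leave a residual dependence of E on the fragmentation. A
`length_adjust = FALSE` flag disables the edge correction entirely for
sensitivity analysis. Second, the database's `total_length` is the raw
residue count; NCBI tools report a length-*adjusted* "effective database
size" that differs slightly. The raw count is exposed because it is
well-defined for any FASTA input and sums exactly over chunks.

## The built-in aligner

To make the pipeline testable end to end without external software, the
package includes an ungapped seed-and-extend nucleotide search backend
(Rcpp): exact-word seeding (default word size 11), X-drop extension
(each direction stops when the running score drops more than `x_drop`
below its maximum, and the span is trimmed to the maximal-scoring
extent), and per-diagonal deduplication of overlapping extensions
keeping the highest score (ties to the leftmost query start). Defaults —
match +1, mismatch −2, word size 11, X-drop 10, minimum raw score 16 —
echo blastn-like ungapped settings; all are configurable, and any
scheme must have negative expected per-position score for the
statistics above to apply. Ambiguity codes (N and the other IUPAC
letters) never participate in seeds and always score as a mismatch —
deterministic and conservative. Only the plus strand is searched by
default; `both_strands = TRUE` also searches each query's reverse
complement and reports such hits with `s_start > s_end`, the BLAST
tabular convention. Gapped alignment, two-hit seeding, masking and
protein alphabets are out of scope.

Tasks can instead delegate to an external command:
`render_external_command()` substitutes `{query}`, `{db}`, `{out}` and
`{dbseqnum}` placeholders per task, and the same template is embedded
(with shell variables) in emitted array scripts — this is how a patched
search binary accepting a database-sequence-count option would be
driven.

## Splitting, checkpointing and merging

Chunking is deterministic greedy byte-packing over serialized record
sizes (header plus 60-column-wrapped sequence): records go to the
current chunk until the next would exceed the budget; an oversized
record sits alone in its chunk. Deterministic packing makes chunk
counts reproducible, unlike splitters that cut on approximate block
boundaries. Chunks are named `<prefix>_1 … <prefix>_M`, and a
plain-text manifest sidecar records index, path, record count and byte
size.

`verify_run()` compares the expected `results.<i1>_<i2>` set against the
directory, maps missing names back to task IDs, and writes `failed.lst`
(one ascending task ID per line), which `run_local()` and
`emit_array_script()` accept as a task filter. Zero-byte files count as
failures by default, because a killed task can leave an empty file; the
flip side is that a *completed* task that found nothing must be
distinguishable, so the built-in backend writes an empty result as a
single blank line (never zero bytes) and the parser skips blank lines.
External backends that produce genuinely empty files can be verified
with `require_nonempty = FALSE`. Unexpected extra files warn but never
fail verification. Result files are written atomically (temp name +
rename), so an interrupted task never leaves a complete-looking file.

Merging re-globalizes every parsed hit (raw scores are recovered by
inverting the bit-score formula — exact, since raw scores are integers
and bit scores are printed to 0.1), filters by E-value (default 10),
deduplicates exact duplicates, and ranks within each query by E
ascending, bit score descending, subject ID, query start — a total
order chosen because partition invariance requires a deterministic
tie-break; queries appear in original query-file order, as a single
unsplit search would report them. The default of 500 hits per query
echoes common search-tool defaults. Whether a production merge should
re-rank or merely concatenate is underdetermined; re-ranking is the
only choice under which per-query top-$k$ selection is well-defined.

## The synthetic fixture generator

`generate_fixture()` emulates, at desk scale, the structure such
searches encounter: a database of i.i.d. uniform-base sequences and
queries of which a chosen fraction carry a planted homology — a
substring copied from a random subject, mutated at rate
$1 - \text{identity}$ (substitutions only, since the backend is
ungapped), at a random offset — with a truth table of every plant. The
defaults (200 subjects of 300–600 bp, 40 queries of 120–200 bp, half
planted at length 40 and identity 0.98) give roughly 100 kb of sequence:
large enough to split 4 × 3 and to exercise every stage in seconds,
which is the problem size the equivalence and restoration tests run at.
All randomness is scoped to an explicit seed (`withr::with_seed`); the
generator never perturbs the caller's RNG state.

What it does *not* emulate: repeats, GC skew, indels, homopolymer
artifacts, and realistic length distributions. Passing tests therefore
demonstrate the pipeline's internal consistency (split/merge
equivalence, checkpoint restoration, statistical correction), not
sensitivity on real genomes.

## Numerical and degenerate-input choices

- $\lambda$ is solved to residual $\le 10^{-9}$; two schemes have
  closed forms used as oracles: +1/−1 gives $\lambda = \ln 3$ and +1/−2
  gives $\lambda = \ln\big((3+\sqrt{21})/2\big)$.
- E-values are printed in scientific notation with 3 significant
  digits, percent identity with 3 decimals, bit scores with 1 decimal;
  E-values are never clamped to zero.
- A record larger than the chunk budget is not an error; it occupies a
  chunk alone. A sub-unit search-space mass ($Kmn < 1$) clamps the
  length adjustment to 0.
- Sequences shorter than the word size yield no seeds (not an error);
  empty inputs, malformed FASTA and malformed tabular lines raise
  classed errors naming the file and line.

## Known limitations

The built-in backend is ungapped and single-threaded per task
(`threads_per_task` is slot-accounting metadata for schedulers);
parallelism comes from the task count, which is the point of the
method. K for exotic scoring schemes relies on series truncation rather
than a closed form. The emitted scripts are not submitted — scheduler
execution, MPI and cloud spot queues are out of scope.
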