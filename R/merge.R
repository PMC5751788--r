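tabular_columns <- c("query_id", "subject_id", "percent_identity",
                     "align_length", "mismatches", "gap_opens",
                     "q_start", "q_end", "s_start", "s_end",
                     "evalue", "bit_score")

#' Write hits in BLAST tabular (outfmt 6) dialect
#'
#' Twelve tab-separated columns per hit: qseqid, sseqid, pident, length,
#' mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore.
#' Percent identity is printed with 3 decimals, the E-value in scientific
#' notation with 3 significant digits, the bit score with 1 decimal.
#'
#' A report with no hits is written as a single blank line rather than a
#' zero-byte file: a completed task that found nothing must remain
#' distinguishable from a killed task, which leaves a zero-byte (or
#' absent) file that [verify_run()] flags for rerun. [parse_tabular()]
#' ignores blank lines.
#'
#' @param hits Ordered hit data.frame.
#' @param path Output path.
#' @return Invisibly, the number of hits written.
#' @export
write_tabular <- function(hits, path) {
  lines <- if (nrow(hits) == 0) "" else
    sprintf("%s\t%s\t%.3f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%.1f",
            hits$query_id, hits$subject_id, hits$percent_identity,
            hits$align_length, hits$mismatches, hits$gap_opens,
            hits$q_start, hits$q_end, hits$s_start, hits$s_end,
            sprintf("%.2e", hits$evalue), hits$bit_score)
  con <- file(path, "wb")  # fixed newline convention across platforms
  on.exit(close(con))
  if (length(lines) > 0) writeLines(lines, con)
  invisible(nrow(hits))
}

#' Parse a partial result file in BLAST tabular (outfmt 6) dialect
#'
#' @param path Result file. An empty file is legitimate (a task may find
#'   nothing) and yields zero hits. The source (i1, i2) pair is recovered
#'   from a `results.<i1>_<i2>` file name when present.
#' @return Hit data.frame (see [search_chunk()]; `raw_score` is `NA` —
#'   it is recovered from the bit score at merge time, when the scoring
#'   parameters are known).
#' @export
parse_tabular <- function(path) {
  if (!file.exists(path))
    dseg_stop(sprintf("result file not found: %s", path),
              "dualseg_error_missing_file")
  out <- empty_hits()
  pair <- tryCatch(parse_result_name(basename(path)), error = function(e) NULL)
  if (file.size(path) == 0) {
    if (!is.null(pair)) { out$i1 <- integer(); out$i2 <- integer() }
    return(out)
  }
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)))  # blank line = completed, no hits
  if (length(keep) == 0) {
    if (!is.null(pair)) { out$i1 <- integer(); out$i2 <- integer() }
    return(out)
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 12)
  if (length(bad) > 0)
    dseg_stop(sprintf("malformed line %d in %s: expected 12 tab-separated columns, got %d",
                      keep[bad[1]], path, lengths(fields)[bad[1]]),
              "dualseg_error_malformed_tabular")
  m <- do.call(rbind, fields)
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(v))
      dseg_stop(sprintf("non-numeric %s at line %d of %s", what,
                        keep[which(is.na(v))[1]], path),
                "dualseg_error_malformed_tabular")
    v
  }
  out <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    percent_identity = num(3, "percent identity"),
    align_length = as.integer(num(4, "alignment length")),
    mismatches = as.integer(num(5, "mismatch count")),
    gap_opens = as.integer(num(6, "gap open count")),
    q_start = as.integer(num(7, "query start")),
    q_end = as.integer(num(8, "query end")),
    s_start = as.integer(num(9, "subject start")),
    s_end = as.integer(num(10, "subject end")),
    evalue = num(11, "E-value"),
    bit_score = num(12, "bit score"),
    raw_score = NA_integer_, stringsAsFactors = FALSE)
  if (!is.null(pair)) { out$i1 <- pair[["i1"]]; out$i2 <- pair[["i2"]] }
  out
}

# Canonical hit ordering: queries in original query-file order, then
# E ascending, bit score descending, subject id, query start — the
# deterministic ranking the partition-invariance guarantee rests on.
canonical_order <- function(hits, query_order) {
  qrank <- match(hits$query_id, query_order)
  order(qrank, hits$evalue, -hits$bit_score, hits$subject_id, hits$q_start,
        hits$s_start)
}

#' Merge the M x N partial results into one globally ranked report
#'
#' Parses every task's `results.<i1>_<i2>` file, recomputes each hit's
#' E-value against the original (unsplit) database via the global
#' search-space statistics, filters by E-value, deduplicates exact
#' duplicates, ranks hits canonically within each query (E ascending,
#' bit score descending, subject id, query start), retains the top `k`
#' per query, and orders queries as in the original query file. Raw
#' scores are recovered by inverting the bit-score formula (raw scores
#' are integers, so the rounding is exact at reported precision).
#'
#' The merged report of a dual-segmented run is identical to the report
#' of an unsplit run of the same pipeline — the method's correctness
#' claim.
#'
#' @param plan The [build_plan()] job plan.
#' @param results_dir Directory of partial results.
#' @param scoring The [scoring_scheme()] used by the run.
#' @param top_k Hits retained per query (`Inf` for all).
#' @param evalue_cutoff Maximum reported E-value.
#' @param base_freqs Background base frequencies.
#' @param length_adjust Apply the edge-effect correction.
#' @return Ordered hit data.frame.
#' @export
merge_results <- function(plan, results_dir, scoring = scoring_scheme(),
                          top_k = 500, evalue_cutoff = 10,
                          base_freqs = rep(0.25, 4), length_adjust = TRUE) {
  report <- verify_run(plan, results_dir)
  if (!report$complete)
    dseg_stop(sprintf(
      "run incomplete: %d partial result(s) missing; run verify_run() and rerun the failed.lst tasks before merging",
      nrow(report$missing)), "dualseg_error_incomplete_run")
  params <- karlin_params(scoring, base_freqs)
  parts <- lapply(plan$tasks$result_name, function(nm)
    parse_tabular(file.path(results_dir, nm)))
  hits <- do.call(rbind, parts)
  queries <- do.call(rbind, lapply(plan$query_chunk_paths, read_fasta))
  query_lengths <- stats::setNames(nchar(queries$seq), queries$id)
  if (nrow(hits) > 0) {
    hits$raw_score <- raw_from_bits(hits$bit_score, params)
    hits <- globalize_hits(hits, plan$global_db_stats, plan$global_db_stats,
                           query_lengths, params,
                           length_adjust = length_adjust)
    hits <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
    key <- paste(hits$query_id, hits$subject_id, hits$q_start, hits$q_end,
                 hits$s_start, hits$s_end, hits$raw_score)
    hits <- hits[!duplicated(key), , drop = FALSE]
    hits <- hits[canonical_order(hits, queries$id), , drop = FALSE]
    if (is.finite(top_k)) {
      keep <- unlist(lapply(split(seq_len(nrow(hits)), hits$query_id),
                            function(ix) utils::head(ix, top_k)),
                     use.names = FALSE)
      hits <- hits[sort(keep), , drop = FALSE]
    }
    rownames(hits) <- NULL
  }
  hits
}
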