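#' Scoring scheme for the built-in ungapped nucleotide aligner
#'
#' Defaults echo blastn-style ungapped scoring: match +1, mismatch -2,
#' word size 11, X-drop 10, minimum reported raw score 16. The expected
#' per-position score under the background base frequencies must be
#' negative for Karlin-Altschul E-value statistics to apply; this is
#' checked when the scheme's statistical parameters are solved.
#'
#' @param match Positive integer match reward.
#' @param mismatch Negative integer mismatch penalty.
#' @param word_size Exact-seed length `w` (>= 4).
#' @param x_drop Non-negative score drop-off ending an extension.
#' @param min_raw_score Raw-score reporting cutoff.
#' @return A `scoring_scheme` object (list).
#' @export
scoring_scheme <- function(match = 1L, mismatch = -2L, word_size = 11L,
                           x_drop = 10L, min_raw_score = 16L) {
  match <- as.integer(match); mismatch <- as.integer(mismatch)
  if (!(match > 0 && mismatch < 0))
    dseg_stop("need match > 0 > mismatch", "dualseg_error_bad_scoring")
  if (word_size < 4)
    dseg_stop("word_size must be >= 4", "dualseg_error_bad_scoring")
  if (x_drop < 0)
    dseg_stop("x_drop must be >= 0", "dualseg_error_bad_scoring")
  structure(list(match = match, mismatch = mismatch,
                 word_size = as.integer(word_size),
                 x_drop = as.integer(x_drop),
                 min_raw_score = as.integer(min_raw_score)),
            class = "scoring_scheme")
}

#' Exact-word seed positions between two sequences
#'
#' Returns every (query, subject) position pair at which the two
#' sequences share an exact `word_size`-mer of unambiguous bases
#' (A/C/G/T). Ambiguity codes never participate in seeds. Positions are
#' 1-based seed starts, ascending by (q_pos, s_pos). A sequence shorter
#' than the word size yields no seeds.
#'
#' @param query_seq,subject_seq Residue strings.
#' @param word_size Seed length.
#' @return Integer matrix with columns `q_pos`, `s_pos`.
#' @export
find_seeds <- function(query_seq, subject_seq, word_size) {
  .cpp_find_seeds(toupper(query_seq), toupper(subject_seq),
                  as.integer(word_size))
}

#' Ungapped X-drop extension of one seed
#'
#' Extends an exact word match left and right independently; each
#' direction stops when the running score falls more than `x_drop` below
#' that direction's maximum or at a sequence end, and the reported span
#' is trimmed back to the maximal-scoring extent. Returns `NULL` when the
#' extended raw score is below `scoring$min_raw_score`.
#'
#' @param query_seq,subject_seq Residue strings.
#' @param q_pos,s_pos 1-based seed start positions (must be an exact
#'   word match).
#' @param scoring A [scoring_scheme()].
#' @return A one-row hit data.frame (without E-value columns), or `NULL`.
#' @export
extend_seed <- function(query_seq, subject_seq, q_pos, s_pos, scoring) {
  e <- .cpp_extend_seed(toupper(query_seq), toupper(subject_seq),
                        as.integer(q_pos), as.integer(s_pos),
                        scoring$word_size, scoring$match, scoring$mismatch,
                        scoring$x_drop)
  if (e$raw_score < scoring$min_raw_score) return(NULL)
  data.frame(q_start = e$q_start, q_end = e$q_end,
             s_start = e$s_start, s_end = e$s_end,
             raw_score = e$raw_score, mismatches = e$mismatches,
             align_length = e$align_length,
             percent_identity = 100 * (e$align_length - e$mismatches) /
               e$align_length)
}

empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             percent_identity = numeric(), align_length = integer(),
             mismatches = integer(), gap_opens = integer(),
             q_start = integer(), q_end = integer(),
             s_start = integer(), s_end = integer(),
             evalue = numeric(), bit_score = numeric(),
             raw_score = integer(), stringsAsFactors = FALSE)
}

#' Search all query records against all database records
#'
#' The built-in BLAST-like backend: for every query x subject pair,
#' exact-word seeds are found, extended without gaps under the X-drop
#' rule, and overlapping extensions on the same diagonal are deduplicated
#' keeping the highest-scoring span. Hits carry raw scores only; E-values
#' and bit scores are `NA` until assigned by [globalize_hits()] (raw
#' scores are per-pair quantities, independent of how the database is
#' partitioned — the property dual segmentation relies on).
#'
#' By default only the plus strand of each query is searched; with
#' `both_strands = TRUE` the reverse complement is searched too and
#' minus-strand hits are reported with `s_start > s_end` (BLAST tabular
#' convention).
#'
#' @param query_records,db_records Record data.frames ([read_fasta()]).
#' @param scoring A [scoring_scheme()].
#' @param both_strands Also search the reverse complement of each query.
#' @return Hit data.frame with columns `query_id`, `subject_id`,
#'   `percent_identity`, `align_length`, `mismatches`, `gap_opens`,
#'   `q_start`, `q_end`, `s_start`, `s_end`, `evalue`, `bit_score`,
#'   `raw_score`.
#' @export
search_chunk <- function(query_records, db_records,
                         scoring = scoring_scheme(),
                         both_strands = FALSE) {
  fasta_check_records(query_records)
  fasta_check_records(db_records)
  qseqs <- toupper(query_records$seq)
  sseqs <- toupper(db_records$seq)
  one_strand <- function(strand) {
    qin <- if (strand == "plus") qseqs else
      vapply(qseqs, revcomp, character(1), USE.NAMES = FALSE)
    h <- .cpp_search_chunk(qin, sseqs, scoring$word_size, scoring$match,
                           scoring$mismatch, scoring$x_drop,
                           scoring$min_raw_score)
    if (nrow(h) == 0) return(NULL)
    if (strand == "minus") {
      # map coordinates of the reverse-complemented query back to the
      # plus-strand query; subject coordinates flip (s_start > s_end)
      L <- nchar(qseqs)[h$query_index]
      qst <- L - h$q_end + 1; qen <- L - h$q_start + 1
      h$q_start <- qst; h$q_end <- qen
      tmp <- h$s_start; h$s_start <- h$s_end; h$s_end <- tmp
    }
    data.frame(
      query_id = query_records$id[h$query_index],
      subject_id = db_records$id[h$subject_index],
      percent_identity = 100 * (h$align_length - h$mismatches) /
        h$align_length,
      align_length = h$align_length, mismatches = h$mismatches,
      gap_opens = 0L,
      q_start = h$q_start, q_end = h$q_end,
      s_start = h$s_start, s_end = h$s_end,
      evalue = NA_real_, bit_score = NA_real_,
      raw_score = h$raw_score,
      query_index = h$query_index, subject_index = h$subject_index,
      stringsAsFactors = FALSE)
  }
  strands <- if (both_strands) c("plus", "minus") else "plus"
  hits <- do.call(rbind, Filter(Negate(is.null), lapply(strands, one_strand)))
  if (is.null(hits)) return(empty_hits())
  hits <- hits[order(hits$query_index, hits$subject_index, hits$q_start,
                     hits$s_start), , drop = FALSE]
  hits$query_index <- NULL
  hits$subject_index <- NULL
  rownames(hits) <- NULL
  hits
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Render an external search command for one task
#'
#' Substitutes a command template's placeholders with the task's chunk
#' paths, result name, and the effective number of sequences of the
#' original database, producing the command line a delegated backend
#' (e.g. a patched `blastn` accepting a database-sequence-count option)
#' would run for that task. The command is returned as text, never
#' executed here.
#'
#' Required placeholders: `{query}`, `{db}`, `{out}`. Optional:
#' `{dbseqnum}` (global `num_sequences`), `{dblen}` (global
#' `total_length`), `{threads}`.
#'
#' @param template Command template text.
#' @param task One row of a plan's `tasks` data.frame (or a list with
#'   `query_chunk_path`, `db_chunk_path`, `result_name`).
#' @param db_stats Global [compute_db_stats()] of the unsplit database.
#' @param threads Threads per task (substituted for `{threads}`).
#' @return The rendered command string.
#' @export
render_external_command <- function(template, task, db_stats, threads = 1L) {
  vals <- c(query = task$query_chunk_path, db = task$db_chunk_path,
            out = task$result_name,
            dbseqnum = format(db_stats$num_sequences, scientific = FALSE),
            dblen = format(db_stats$total_length, scientific = FALSE),
            threads = as.character(threads))
  required <- c("query", "db", "out")
  miss <- required[!vapply(required, function(p)
    grepl(sprintf("{%s}", p), template, fixed = TRUE), logical(1))]
  if (length(miss) > 0)
    dseg_stop(paste("template missing required placeholder(s):",
                    paste0("{", miss, "}", collapse = ", ")),
              "dualseg_error_bad_template")
  found <- regmatches(template, gregexpr("\\{[^}{]*\\}", template))[[1]]
  unknown <- setdiff(unique(gsub("[{}]", "", found)), names(vals))
  if (length(unknown) > 0)
    dseg_stop(paste("unknown placeholder(s):",
                    paste0("{", unknown, "}", collapse = ", ")),
              "dualseg_error_bad_template")
  for (p in names(vals))
    template <- gsub(sprintf("{%s}", p), vals[[p]], template, fixed = TRUE)
  template
}
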