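#' Generate a deterministic synthetic query/database fixture
#'
#' Builds a database of i.i.d. uniform-base nucleotide sequences and a
#' query set in which a chosen fraction of queries carry a planted
#' homology: a substring of length `planted_len` copied from a randomly
#' chosen subject, mutated at a per-base substitution rate of
#' `1 - planted_identity` (substitutions only — the built-in aligner is
#' ungapped), and inserted at a random offset. The remaining queries are
#' pure background. A truth table records every plant. Everything is
#' reproducible from `seed`; the generator never touches the caller's
#' random state.
#'
#' The defaults emulate the package's desk-scale study conditions: 40
#' queries against 200 subjects (about 100 kb of sequence in total) with
#' half the queries carrying a 40-residue plant at 98% identity — large
#' enough that every stage of the pipeline and the split-vs-unsplit
#' equivalence check run in seconds, while still exercising multi-chunk
#' splits in both dimensions.
#'
#' @param n_db Number of database sequences.
#' @param n_query Number of query sequences.
#' @param db_len_range,query_len_range Length ranges (min, max) in
#'   residues, sampled uniformly.
#' @param planted_fraction Fraction of queries receiving a plant.
#' @param planted_len Plant length in residues (must fit the shortest
#'   query).
#' @param planted_identity Expected identity of the plant, between 0 and 1.
#' @param seed Integer seed.
#' @return List with record data.frames `query` and `db`, and `truth`
#'   (data.frame: `query_id`, `subject_id`, `q_start`, `q_end`,
#'   `s_start`, `s_end`).
#' @export
generate_fixture <- function(n_db = 200L, n_query = 40L,
                             db_len_range = c(300L, 600L),
                             query_len_range = c(120L, 200L),
                             planted_fraction = 0.5, planted_len = 40L,
                             planted_identity = 0.98, seed = 1L) {
  if (planted_len > query_len_range[1])
    dseg_stop("planted_len must fit the shortest query",
              "dualseg_error_bad_fixture")
  if (db_len_range[1] > db_len_range[2] ||
      query_len_range[1] > query_len_range[2])
    dseg_stop("length ranges must be (min, max) with min <= max",
              "dualseg_error_bad_fixture")
  if (planted_len > db_len_range[1])
    dseg_stop("planted_len must fit the shortest subject",
              "dualseg_error_bad_fixture")
  bases <- c("A", "C", "G", "T")
  withr::with_seed(as.integer(seed), {
    rand_seq <- function(len)
      paste(sample(bases, len, replace = TRUE), collapse = "")
    db_len <- sample(db_len_range[1]:db_len_range[2], n_db, replace = TRUE)
    db <- data.frame(id = sprintf("subject_%03d", seq_len(n_db)),
                     desc = "synthetic background",
                     seq = vapply(db_len, rand_seq, character(1)),
                     stringsAsFactors = FALSE)
    q_len <- sample(query_len_range[1]:query_len_range[2], n_query,
                    replace = TRUE)
    query <- data.frame(id = sprintf("query_%03d", seq_len(n_query)),
                        desc = "synthetic background",
                        seq = vapply(q_len, rand_seq, character(1)),
                        stringsAsFactors = FALSE)
    n_plant <- round(planted_fraction * n_query)
    planted <- if (n_plant > 0) sort(sample(n_query, n_plant)) else integer()
    truth <- data.frame(query_id = character(), subject_id = character(),
                        q_start = integer(), q_end = integer(),
                        s_start = integer(), s_end = integer(),
                        stringsAsFactors = FALSE)
    for (qi in planted) {
      si <- sample(n_db, 1)
      s_start <- sample(nchar(db$seq[si]) - planted_len + 1, 1)
      frag <- strsplit(substr(db$seq[si], s_start,
                              s_start + planted_len - 1), "")[[1]]
      mut <- which(stats::runif(planted_len) > planted_identity)
      for (k in mut)
        frag[k] <- sample(setdiff(bases, frag[k]), 1)
      q_start <- sample(q_len[qi] - planted_len + 1, 1)
      substr(query$seq[qi], q_start, q_start + planted_len - 1) <-
        paste(frag, collapse = "")
      query$desc[qi] <- sprintf("planted from %s", db$id[si])
      truth <- rbind(truth, data.frame(
        query_id = query$id[qi], subject_id = db$id[si],
        q_start = q_start, q_end = q_start + planted_len - 1L,
        s_start = s_start, s_end = s_start + planted_len - 1L,
        stringsAsFactors = FALSE))
    }
    list(query = query, db = db, truth = truth)
  })
}

#' Write a generated fixture to disk
#'
#' Writes `query.fasta`, `db.fasta` and `truth.tsv` into a directory.
#'
#' @param fixture A [generate_fixture()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(fixture$query, file.path(dir, "query.fasta"))
  write_fasta(fixture$db, file.path(dir, "db.fasta"))
  utils::write.table(fixture$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
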