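# Shared helpers: tiny record constructors and brute-force oracles.

records_df <- function(ids, seqs, descs = rep("", length(ids))) {
  data.frame(id = ids, desc = descs, seq = seqs, stringsAsFactors = FALSE)
}

random_records <- function(n, len_range = c(20, 120), prefix = "r",
                           seed = 101) {
  withr::with_seed(seed, {
    lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
    records_df(sprintf("%s%03d", prefix, seq_len(n)),
               vapply(lens, function(L)
                 paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                       collapse = ""), character(1)),
               descs = ifelse(seq_len(n) %% 2 == 0, "even record", ""))
  })
}

write_fasta_text <- function(text, dir = tempdir()) {
  path <- tempfile("fa", tmpdir = dir, fileext = ".fasta")
  writeLines(text, path, sep = "")
  path
}

# O(L^2) brute-force seed oracle: all exact unambiguous w-mer matches.
brute_seeds <- function(q, s, w) {
  out <- NULL
  for (i in seq_len(max(0, nchar(q) - w + 1))) {
    qi <- substr(q, i, i + w - 1)
    if (grepl("[^ACGT]", qi)) next
    for (j in seq_len(max(0, nchar(s) - w + 1))) {
      if (qi == substr(s, j, j + w - 1))
        out <- rbind(out, c(i, j))
    }
  }
  if (is.null(out)) matrix(integer(), ncol = 2) else out
}

# Recompute a hit's raw score and mismatch count from the sequences.
rescore_hit <- function(hit, qseq, sseq, scoring) {
  qs <- strsplit(substr(qseq, hit$q_start, hit$q_end), "")[[1]]
  ss <- strsplit(substr(sseq, hit$s_start, hit$s_end), "")[[1]]
  match <- qs == ss & qs %in% c("A", "C", "G", "T")
  list(raw_score = sum(ifelse(match, scoring$match, scoring$mismatch)),
       mismatches = sum(!match))
}

# Small end-to-end fixture shared by orchestrator/merge tests.
small_fixture_dir <- function(seed = 11, n_db = 40, n_query = 10) {
  fx <- generate_fixture(n_db = n_db, n_query = n_query,
                         db_len_range = c(150, 300),
                         query_len_range = c(100, 160),
                         planted_fraction = 0.5, planted_len = 40,
                         planted_identity = 1.0, seed = seed)
  dir <- tempfile("fix")
  write_fixture(fx, dir)
  list(dir = dir, fixture = fx,
       query = file.path(dir, "query.fasta"),
       db = file.path(dir, "db.fasta"))
}
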