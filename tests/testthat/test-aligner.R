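test_that("identical sequences seed along the full main diagonal", {
  s <- "ACGTGCTAGCTAGGATCCGATG"
  w <- 11
  seeds <- find_seeds(s, s, w)
  expect_equal(nrow(seeds), nchar(s) - w + 1)
  expect_equal(seeds[, "q_pos"], seeds[, "s_pos"])
})

test_that("sequences with no shared word yield no seeds", {
  a <- paste(rep("A", 40), collapse = "")
  c <- paste(rep("C", 40), collapse = "")
  expect_equal(nrow(find_seeds(a, c, 11)), 0)
  # shorter than the word size: empty result, not an error
  expect_equal(nrow(find_seeds("ACGT", a, 11)), 0)
})

test_that("seed finding matches the brute-force all-pairs oracle", {
  withr::with_seed(5, {
    for (rep in 1:5) {
      q <- paste(sample(c("A", "C", "G", "T", "N"), 200, replace = TRUE,
                        prob = c(.24, .24, .24, .24, .04)), collapse = "")
      s <- paste(sample(c("A", "C", "G", "T", "N"), 200, replace = TRUE,
                        prob = c(.24, .24, .24, .24, .04)), collapse = "")
      w <- sample(4:8, 1)
      got <- find_seeds(q, s, w)
      want <- brute_seeds(q, s, w)
      got <- got[order(got[, 1], got[, 2]), , drop = FALSE]
      want <- want[order(want[, 1], want[, 2]), , drop = FALSE]
      expect_equal(unname(got), unname(want))
    }
  })
})

test_that("extension over identical sequences spans everything", {
  s <- paste(withr::with_seed(9, sample(c("A", "C", "G", "T"), 50,
                                        replace = TRUE)), collapse = "")
  sc <- scoring_scheme(match = 1, mismatch = -2, word_size = 11)
  for (pos in c(1, 17, 40)) {
    h <- extend_seed(s, s, pos, pos, sc)
    expect_equal(h$q_start, 1); expect_equal(h$q_end, 50)
    expect_equal(h$s_start, 1); expect_equal(h$s_end, 50)
    expect_equal(h$raw_score, 50)
    expect_equal(h$percent_identity, 100)
  }
})

test_that("X-drop trims the reported span to the planted exact island", {
  # 30-mer exact match flanked by unrelated sequence on both sides
  withr::with_seed(33, {
    island <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                    collapse = "")
    q <- paste0(paste(rep("A", 20), collapse = ""), island,
                paste(rep("A", 20), collapse = ""))
    s <- paste0(paste(rep("C", 20), collapse = ""), island,
                paste(rep("C", 20), collapse = ""))
  })
  sc <- scoring_scheme(match = 1, mismatch = -2, word_size = 11, x_drop = 3)
  h <- extend_seed(q, s, 21, 21, sc)
  expect_equal(c(h$q_start, h$q_end), c(21, 50))
  expect_equal(h$raw_score, 30)
  expect_equal(h$mismatches, 0)
})

test_that("extension below the reporting cutoff returns NULL", {
  s <- "ACGTACGTACGTACG"
  sc <- scoring_scheme(word_size = 11, min_raw_score = 1000)
  expect_null(extend_seed(s, s, 1, 1, sc))
  expect_error(extend_seed(s, s, 1, 3, sc))  # not an exact word match
})

test_that("search_chunk finds the self-match and nothing across alphabets", {
  withr::with_seed(14, {
    s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
               collapse = "")
  })
  recs <- records_df("x", s)
  hits <- search_chunk(recs, recs)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$percent_identity, 100)
  expect_equal(c(hits$q_start, hits$q_end), c(1, 60))
  expect_equal(hits$raw_score, 60)
  expect_true(is.na(hits$evalue))   # E-values unset until globalized

  other <- records_df("y", paste(rep("A", 60), collapse = ""))
  expect_equal(nrow(search_chunk(recs, other)), 0)
})

test_that("planted 40-mers are each query's best hit", {
  fx <- generate_fixture(n_db = 5, n_query = 5, db_len_range = c(200, 300),
                         query_len_range = c(100, 120),
                         planted_fraction = 1, planted_len = 40,
                         planted_identity = 1, seed = 77)
  hits <- search_chunk(fx$query, fx$db)
  expect_gte(nrow(hits), 5)
  for (i in seq_len(nrow(fx$truth))) {
    qh <- hits[hits$query_id == fx$truth$query_id[i], ]
    best <- qh[which.max(qh$raw_score), ]
    expect_equal(best$subject_id, fx$truth$subject_id[i])
    expect_gte(best$raw_score, 40)
  }
})

test_that("emitted hits satisfy the ungapped coordinate and rescoring invariants", {
  fx <- generate_fixture(n_db = 15, n_query = 8, db_len_range = c(150, 250),
                         query_len_range = c(100, 140),
                         planted_fraction = 0.6, planted_len = 45,
                         planted_identity = 0.9, seed = 19)
  sc <- scoring_scheme()
  hits <- search_chunk(fx$query, fx$db, sc)
  expect_gt(nrow(hits), 0)
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    expect_gte(h$q_end, h$q_start)
    expect_gte(h$s_end, h$s_start)
    expect_equal(h$q_end - h$q_start, h$s_end - h$s_start)
    re <- rescore_hit(h, fx$query$seq[fx$query$id == h$query_id],
                      fx$db$seq[fx$db$id == h$subject_id], sc)
    expect_equal(h$raw_score, re$raw_score)
    expect_equal(h$mismatches, re$mismatches)
    expect_equal(h$percent_identity,
                 100 * (h$align_length - h$mismatches) / h$align_length)
  }
})

test_that("raw hits are invariant under partitioning the database", {
  fx <- generate_fixture(n_db = 20, n_query = 6, db_len_range = c(150, 250),
                         query_len_range = c(100, 140),
                         planted_fraction = 0.5, planted_len = 40,
                         planted_identity = 0.95, seed = 4)
  whole <- search_chunk(fx$query, fx$db)
  key <- function(h) {
    k <- paste(h$query_id, h$subject_id, h$q_start, h$q_end, h$s_start,
               h$s_end, h$raw_score)
    sort(k)
  }
  for (cut in c(5, 10, 17)) {
    a <- search_chunk(fx$query, fx$db[1:cut, ])
    b <- search_chunk(fx$query, fx$db[(cut + 1):20, ])
    expect_equal(key(rbind(a, b)), key(whole))
  }
})

test_that("reverse-complement search reports minus-strand subject coordinates", {
  withr::with_seed(55, {
    sub <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
                 collapse = "")
  })
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sub)))
  q <- records_df("q", substr(rc, 11, 50))
  s <- records_df("s", sub)
  expect_equal(nrow(search_chunk(q, s)), 0)  # plus-only misses it
  hits <- search_chunk(q, s, both_strands = TRUE)
  expect_equal(nrow(hits), 1)
  expect_gt(hits$s_start, hits$s_end)        # minus strand convention
  expect_equal(hits$percent_identity, 100)
  expect_equal(hits$q_start, 1)
  expect_equal(hits$q_end, 40)
})

test_that("render_external_command substitutes placeholders verbatim", {
  task <- list(query_chunk_path = "q/split/query_3",
               db_chunk_path = "db/split/db_7",
               result_name = "results.3_7")
  stats <- structure(list(num_sequences = 523449, total_length = 2457100615),
                     class = "db_stats")
  cmd <- render_external_command(
    "search -q {query} -d {db} -o {out} -dbseqnum {dbseqnum}", task, stats)
  expect_match(cmd, "-dbseqnum 523449", fixed = TRUE)
  expect_match(cmd, "-q q/split/query_3", fixed = TRUE)
  expect_match(cmd, "-o results.3_7", fixed = TRUE)
  # substitution is pure text: rendering twice yields identical strings
  expect_identical(cmd, render_external_command(
    "search -q {query} -d {db} -o {out} -dbseqnum {dbseqnum}", task, stats))
  expect_error(render_external_command("search -q {query} -d {db}", task,
                                       stats),
               class = "dualseg_error_bad_template")
  expect_error(render_external_command("x {query} {db} {out} {bogus}", task,
                                       stats),
               class = "dualseg_error_bad_template")
})
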