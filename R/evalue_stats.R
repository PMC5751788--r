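#' Karlin-Altschul statistics for the ungapped match/mismatch model
#'
#' Under a match/mismatch scoring scheme and background base frequencies
#' p, the score statistics of chance ungapped local alignments follow the
#' Karlin-Altschul theory: lambda is the unique positive root of
#' `sum_ij p_i p_j exp(lambda * s_ij) = 1`, H is the relative entropy per
#' aligned position, and K scales the search space. Bit scores are
#' `S' = (lambda*S - ln K)/ln 2` and the expected number of chance hits
#' scoring at least S' in a search space of effective size m' x n' is
#' `E = m' n' 2^(-S')`.
#'
#' @name karlin
NULL

# Per-position score distribution: P(score = match) = sum(p_i^2) only when
# both residues are the same base; everything else is a mismatch.
score_pmf <- function(scoring, base_freqs) {
  if (abs(sum(base_freqs) - 1) > 1e-12)
    dseg_stop("base frequencies must sum to 1", "dualseg_error_bad_freqs")
  if (length(base_freqs) != 4 || any(base_freqs < 0))
    dseg_stop("base_freqs must be a non-negative probability 4-vector",
              "dualseg_error_bad_freqs")
  p_match <- sum(base_freqs^2)
  scores <- c(scoring$mismatch, scoring$match)
  probs <- c(1 - p_match, p_match)
  list(scores = scores, probs = probs,
       expected = sum(scores * probs))
}

#' Solve the Karlin-Altschul lambda for a scoring scheme
#'
#' Finds the unique positive root of
#' `sum_ij p_i p_j exp(lambda * s_ij) = 1` by bracketed root-finding.
#' Requires a negative expected per-position score and a positive maximum
#' score, the usual conditions for local-alignment statistics.
#'
#' @param scoring A [scoring_scheme()].
#' @param base_freqs Background base frequency 4-vector (A, C, G, T);
#'   defaults to uniform.
#' @return `lambda` in nats per score unit; the defining equation holds
#'   to an absolute residual below 1e-9.
#' @export
solve_lambda <- function(scoring, base_freqs = rep(0.25, 4)) {
  pmf <- score_pmf(scoring, base_freqs)
  if (pmf$expected >= 0)
    dseg_stop("expected per-position score must be negative (no positive lambda root)",
              "dualseg_error_nonnegative_expected_score")
  f <- function(lam) sum(pmf$probs * exp(lam * pmf$scores)) - 1
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  lam <- uniroot(f, c(1e-12, hi), tol = 1e-14)$root
  if (abs(f(lam)) > 1e-9)  # polish with one Newton step if uniroot stopped early
    lam <- lam - f(lam) / sum(pmf$probs * pmf$scores * exp(lam * pmf$scores))
  lam
}

# K values for common blastn-style ungapped (match, mismatch) pairs under
# uniform base frequencies, as tabulated in the standard ungapped
# nucleotide parameter sets.
k_table <- data.frame(
  match = c(1L, 1L, 1L, 1L),
  mismatch = c(-2L, -3L, -4L, -5L),
  k = c(0.621, 0.711, 0.738, 0.747))

# General K via the renewal-theory series: with sigma the excursion sum
#   sigma = sum_{j>=1} (1/j) [ E(e^{lambda S_j}; S_j < 0) + P(S_j >= 0) ]
# over partial sums S_j of j per-position scores, and d the lattice span
# of the score values,
#   K = d * lambda * exp(-2 sigma) / (H * (1 - exp(-lambda d))).
# The series terms decay geometrically (the walk has negative drift);
# it is truncated when a term falls below 1e-12.
karlin_k_series <- function(pmf, lambda, h, max_terms = 400L) {
  d <- Reduce(function(x, y) { while (y) { t <- x %% y; x <- y; y <- t }; x },
              abs(pmf$scores))
  lo1 <- min(pmf$scores)
  p1 <- numeric(max(pmf$scores) - lo1 + 1)
  p1[pmf$scores - lo1 + 1] <- pmf$probs
  sigma <- 0
  pj <- p1; lo <- lo1
  for (j in seq_len(max_terms)) {
    s <- seq(lo, by = 1, length.out = length(pj))
    neg <- s < 0
    term <- sum(pj[neg] * exp(lambda * s[neg])) + sum(pj[!neg])
    sigma <- sigma + term / j
    if (term / j < 1e-12) break
    # next convolution, direct (exact, no FFT round-off)
    nxt <- numeric(length(pj) + length(p1) - 1)
    for (i in seq_along(p1))
      if (p1[i] > 0)
        nxt[i:(i + length(pj) - 1)] <- nxt[i:(i + length(pj) - 1)] + p1[i] * pj
    pj <- nxt; lo <- lo + lo1
  }
  d * lambda * exp(-2 * sigma) / (h * (1 - exp(-lambda * d)))
}

#' Karlin-Altschul parameters (lambda, K, H) of a scoring scheme
#'
#' `lambda` is solved by [solve_lambda()]; `H = lambda * sum q_ij s_ij`
#' with `q_ij = p_i p_j exp(lambda s_ij)` (the target frequencies); `K`
#' comes from a bundled table of standard ungapped nucleotide constants
#' for known (match, mismatch) pairs under uniform frequencies, otherwise
#' from the renewal-series computation (documented at `karlin_k_series`),
#' which reproduces the tabled constants to 3 decimals.
#'
#' @inheritParams solve_lambda
#' @return A `karlin_params` object: list with `lambda`, `k`, `h`.
#' @export
karlin_params <- function(scoring, base_freqs = rep(0.25, 4)) {
  pmf <- score_pmf(scoring, base_freqs)
  lambda <- solve_lambda(scoring, base_freqs)
  q <- pmf$probs * exp(lambda * pmf$scores)
  h <- lambda * sum(q * pmf$scores)
  uniform <- all(abs(base_freqs - 0.25) < 1e-12)
  hit <- uniform & k_table$match == scoring$match &
    k_table$mismatch == scoring$mismatch
  k <- if (any(hit)) k_table$k[which(hit)[1]]
       else karlin_k_series(pmf, lambda, h)
  structure(list(lambda = lambda, k = k, h = h), class = "karlin_params")
}

#' @export
print.karlin_params <- function(x, ...) {
  cat(sprintf("Karlin-Altschul parameters: lambda = %.6f, K = %.4g, H = %.4f\n",
              x$lambda, x$k, x$h))
  invisible(x)
}

#' Length adjustment (edge-effect correction)
#'
#' The expected length of a chance high-scoring alignment is subtracted
#' from the query length and, once per sequence, from the database length
#' before the search space is formed. Computed by the standard fixed-point
#' iteration `l <- ln(K (m - l)(n - N l)) / H` from `l = 0`, at most 20
#' iterations, stopping when the update moves less than 0.5; the result is
#' clamped so the effective query length stays >= 1 and the effective
#' database length stays >= N, then floored to an integer.
#'
#' @param m Query length in residues.
#' @param db_stats [compute_db_stats()] of the database the E-value is
#'   computed against.
#' @param params [karlin_params()].
#' @return Integer length adjustment `l >= 0`.
#' @export
length_adjustment <- function(m, db_stats, params) {
  n <- db_stats$total_length
  nseq <- db_stats$num_sequences
  clamp <- function(l) max(0, min(l, m - 1, (n - nseq) / nseq))
  l <- 0
  for (it in seq_len(20)) {
    mass <- params$k * (m - l) * (n - nseq * l)
    l_new <- if (mass < 1) 0 else clamp(log(mass) / params$h)
    if (abs(l_new - l) < 0.5) { l <- l_new; break }
    l <- l_new
  }
  as.integer(floor(clamp(l)))
}

#' Effective search space for one query against a database
#'
#' @param query_length Query length `m` in residues.
#' @param db_stats Database statistics (total length `n` and effective
#'   number of sequences `N`).
#' @param params [karlin_params()].
#' @param length_adjust Apply the edge-effect correction (default TRUE).
#'   Disabling it (l = 0) supports sensitivity analysis of the
#'   fragment-to-global E-value correction.
#' @return A `search_space` list: `m`, `n`, `num_sequences`,
#'   `length_adjustment`, `effective_m`, `effective_n`.
#' @export
search_space <- function(query_length, db_stats, params,
                         length_adjust = TRUE) {
  l <- if (length_adjust) length_adjustment(query_length, db_stats, params)
       else 0L
  list(m = query_length, n = db_stats$total_length,
       num_sequences = db_stats$num_sequences,
       length_adjustment = l,
       effective_m = max(1, query_length - l),
       effective_n = max(db_stats$num_sequences,
                         db_stats$total_length - db_stats$num_sequences * l))
}

#' Bit score of a raw alignment score
#'
#' `S' = (lambda * S - ln K) / ln 2`.
#'
#' @param raw_score Integer raw score(s).
#' @param params [karlin_params()].
#' @return Bit score(s).
#' @export
bit_score <- function(raw_score, params) {
  (params$lambda * raw_score - log(params$k)) / log(2)
}

raw_from_bits <- function(bits, params) {
  as.integer(round((bits * log(2) + log(params$k)) / params$lambda))
}

#' Expect value of a bit score in a search space
#'
#' `E = m' * n' * 2^(-S')`: the expected number of chance hits scoring at
#' least this well. Never clamped to zero.
#'
#' @param bits Bit score(s).
#' @param space A [search_space()].
#' @return E-value(s).
#' @export
evalue <- function(bits, space) {
  space$effective_m * space$effective_n * 2^(-bits)
}

#' Re-globalize fragment hits to the original database
#'
#' The statistical heart of dual segmentation: a hit found while
#' searching a database *fragment* must be assigned the E-value it would
#' have received against the *whole* database. Each hit's bit score is
#' recomputed from its raw score, the search space is built from the
#' global database statistics (total length and effective number of
#' sequences — both enter the length adjustment and the search-space
#' product), and the E-value is replaced. Coordinates, identities and
#' raw scores are never changed.
#'
#' When `fragment_stats` equals `global_stats` this reduces to the plain
#' per-fragment computation, so an unsplit run takes exactly the same
#' code path.
#'
#' @param hits Hit data.frame from [search_chunk()] (must carry
#'   `raw_score`).
#' @param fragment_stats [compute_db_stats()] of the fragment that was
#'   searched. Must not exceed `global_stats` in either field.
#' @param global_stats [compute_db_stats()] of the original database.
#' @param query_lengths Named integer vector: length of each query id
#'   appearing in `hits`.
#' @param params [karlin_params()].
#' @param length_adjust Passed to [search_space()].
#' @return `hits` with `bit_score` and `evalue` filled in.
#' @export
globalize_hits <- function(hits, fragment_stats, global_stats,
                           query_lengths, params, length_adjust = TRUE) {
  if (fragment_stats$num_sequences > global_stats$num_sequences ||
      fragment_stats$total_length > global_stats$total_length)
    dseg_stop("fragment statistics exceed global database statistics",
              "dualseg_error_fragment_exceeds_global")
  if (nrow(hits) == 0) return(hits)
  missing_q <- setdiff(unique(hits$query_id), names(query_lengths))
  if (length(missing_q) > 0)
    dseg_stop(paste("no query length for:", paste(missing_q, collapse = ", ")),
              "dualseg_error_bad_query_lengths")
  hits$bit_score <- bit_score(hits$raw_score, params)
  for (qid in unique(hits$query_id)) {
    sel <- hits$query_id == qid
    sp <- search_space(query_lengths[[qid]], global_stats, params,
                       length_adjust = length_adjust)
    hits$evalue[sel] <- evalue(hits$bit_score[sel], sp)
  }
  hits
}
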