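#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// 2-bit encoding of unambiguous bases; -1 for anything else (N and the
// other IUPAC ambiguity codes never participate in seeds and always score
// as mismatch).
static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// Score of aligning query char a against subject char b: a match only
// when both are the same unambiguous base.
static inline int pos_score(char a, char b, int match, int mismatch) {
  int ca = base_code(a), cb = base_code(b);
  return (ca >= 0 && ca == cb) ? match : mismatch;
}

typedef std::unordered_map<std::uint64_t, std::vector<int> > WordIndex;

// Index all unambiguous w-mers of a sequence: word value -> 0-based starts.
static WordIndex index_words(const std::string& s, int w) {
  WordIndex idx;
  int L = (int)s.size();
  if (L < w) return idx;
  std::uint64_t word = 0, mask = (w >= 32) ? ~0ULL : ((1ULL << (2 * w)) - 1);
  int run = 0;  // length of current unambiguous run
  for (int i = 0; i < L; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { run = 0; word = 0; continue; }
    word = ((word << 2) | (std::uint64_t)c) & mask;
    if (++run >= w) idx[word].push_back(i - w + 1);
  }
  return idx;
}

struct Seed { int q, s; };  // 0-based starts

static std::vector<Seed> seeds_of(const std::string& q, const std::string& s,
                                  int w) {
  std::vector<Seed> out;
  int Lq = (int)q.size(), Ls = (int)s.size();
  if (Lq < w || Ls < w) return out;
  WordIndex idx = index_words(s, w);
  std::uint64_t word = 0, mask = (w >= 32) ? ~0ULL : ((1ULL << (2 * w)) - 1);
  int run = 0;
  for (int i = 0; i < Lq; ++i) {
    int c = base_code(q[i]);
    if (c < 0) { run = 0; word = 0; continue; }
    word = ((word << 2) | (std::uint64_t)c) & mask;
    if (++run >= w) {
      WordIndex::const_iterator it = idx.find(word);
      if (it != idx.end())
        for (size_t k = 0; k < it->second.size(); ++k) {
          Seed sd; sd.q = i - w + 1; sd.s = it->second[k];
          out.push_back(sd);
        }
    }
  }
  return out;  // ascending by (q, s): q outer, positions stored ascending
}

// [[Rcpp::export(name = ".cpp_find_seeds")]]
IntegerMatrix cpp_find_seeds(std::string query, std::string subject, int w) {
  if (w < 1) stop("word size must be >= 1");
  std::vector<Seed> sd = seeds_of(query, subject, w);
  IntegerMatrix out((int)sd.size(), 2);
  for (size_t i = 0; i < sd.size(); ++i) {
    out(i, 0) = sd[i].q + 1;
    out(i, 1) = sd[i].s + 1;
  }
  colnames(out) = CharacterVector::create("q_pos", "s_pos");
  return out;
}

struct Extension {
  int q_start, q_end, s_start, s_end;  // 0-based inclusive
  int score, mismatches, length;
};

// Ungapped X-drop extension of an exact w-mer seed. Each direction stops
// when the running score falls more than x_drop below that direction's
// running maximum (or at a sequence end); the reported span is trimmed to
// the maximal-scoring extent.
static Extension extend_one(const std::string& q, const std::string& s,
                            int qp, int sp, int w,
                            int match, int mismatch, int x_drop) {
  int Lq = (int)q.size(), Ls = (int)s.size();
  // right of the seed
  int cur = 0, best = 0, best_k = 0, mis = 0, best_mis = 0;
  for (int k = 1; qp + w - 1 + k < Lq && sp + w - 1 + k < Ls; ++k) {
    int sc = pos_score(q[qp + w - 1 + k], s[sp + w - 1 + k], match, mismatch);
    cur += sc;
    if (sc != match) ++mis;
    if (cur > best) { best = cur; best_k = k; best_mis = mis; }
    if (cur < best - x_drop) break;
  }
  int rgain = best, rext = best_k, rmis = best_mis;
  // left of the seed
  cur = 0; best = 0; best_k = 0; mis = 0; best_mis = 0;
  for (int k = 1; qp - k >= 0 && sp - k >= 0; ++k) {
    int sc = pos_score(q[qp - k], s[sp - k], match, mismatch);
    cur += sc;
    if (sc != match) ++mis;
    if (cur > best) { best = cur; best_k = k; best_mis = mis; }
    if (cur < best - x_drop) break;
  }
  Extension e;
  e.q_start = qp - best_k; e.s_start = sp - best_k;
  e.q_end = qp + w - 1 + rext; e.s_end = sp + w - 1 + rext;
  e.score = w * match + best + rgain;
  e.mismatches = best_mis + rmis;
  e.length = e.q_end - e.q_start + 1;
  return e;
}

// [[Rcpp::export(name = ".cpp_extend_seed")]]
List cpp_extend_seed(std::string query, std::string subject,
                     int q_pos, int s_pos, int w,
                     int match, int mismatch, int x_drop) {
  int Lq = (int)query.size(), Ls = (int)subject.size();
  if (q_pos < 1 || s_pos < 1 || q_pos + w - 1 > Lq || s_pos + w - 1 > Ls)
    stop("seed coordinates out of range");
  for (int k = 0; k < w; ++k) {
    int a = base_code(query[q_pos - 1 + k]);
    int b = base_code(subject[s_pos - 1 + k]);
    if (a < 0 || a != b) stop("seed positions are not an exact word match");
  }
  Extension e = extend_one(query, subject, q_pos - 1, s_pos - 1, w,
                           match, mismatch, x_drop);
  return List::create(
    _["q_start"] = e.q_start + 1, _["q_end"] = e.q_end + 1,
    _["s_start"] = e.s_start + 1, _["s_end"] = e.s_end + 1,
    _["raw_score"] = e.score, _["mismatches"] = e.mismatches,
    _["align_length"] = e.length);
}

// Shared per-pair search core used by the single-pair and whole-chunk
// entry points below.
static std::vector<Extension> search_pair_core(const std::string& query,
                                               const std::string& subject,
                                               const WordIndex& idx, int w,
                                               int match, int mismatch,
                                               int x_drop, int min_raw_score) {
  std::vector<Seed> sd;
  {
    int Lq = (int)query.size(), Ls = (int)subject.size();
    if (Lq >= w && Ls >= w) {
      std::uint64_t word = 0,
          mask = (w >= 32) ? ~0ULL : ((1ULL << (2 * w)) - 1);
      int run = 0;
      for (int i = 0; i < Lq; ++i) {
        int c = base_code(query[i]);
        if (c < 0) { run = 0; word = 0; continue; }
        word = ((word << 2) | (std::uint64_t)c) & mask;
        if (++run >= w) {
          WordIndex::const_iterator it = idx.find(word);
          if (it != idx.end())
            for (size_t k = 0; k < it->second.size(); ++k) {
              Seed s; s.q = i - w + 1; s.s = it->second[k];
              sd.push_back(s);
            }
        }
      }
    }
  }
  std::unordered_map<int, int> covered;
  std::vector<Extension> cand;
  for (size_t i = 0; i < sd.size(); ++i) {
    int d = sd[i].s - sd[i].q;
    std::unordered_map<int, int>::iterator it = covered.find(d);
    if (it != covered.end() && sd[i].q + w - 1 <= it->second) continue;
    Extension e = extend_one(query, subject, sd[i].q, sd[i].s, w,
                             match, mismatch, x_drop);
    covered[d] = e.q_end;
    cand.push_back(e);
  }
  std::unordered_map<int, std::vector<int> > by_diag;
  for (size_t i = 0; i < cand.size(); ++i)
    by_diag[cand[i].s_start - cand[i].q_start].push_back((int)i);
  std::vector<Extension> kept;
  for (std::unordered_map<int, std::vector<int> >::iterator dg = by_diag.begin();
       dg != by_diag.end(); ++dg) {
    std::vector<int>& ix = dg->second;
    for (size_t a = 0; a < ix.size(); ++a)
      for (size_t b = a + 1; b < ix.size(); ++b) {
        const Extension& A = cand[ix[a]];
        const Extension& B = cand[ix[b]];
        if (B.score > A.score ||
            (B.score == A.score && B.q_start < A.q_start)) {
          int t = ix[a]; ix[a] = ix[b]; ix[b] = t;
        }
      }
    std::vector<int> taken;
    for (size_t a = 0; a < ix.size(); ++a) {
      const Extension& E = cand[ix[a]];
      bool overlaps = false;
      for (size_t t = 0; t < taken.size(); ++t) {
        const Extension& K = cand[taken[t]];
        if (E.q_start <= K.q_end && K.q_start <= E.q_end) {
          overlaps = true; break;
        }
      }
      if (!overlaps) taken.push_back(ix[a]);
    }
    for (size_t t = 0; t < taken.size(); ++t)
      if (cand[taken[t]].score >= min_raw_score)
        kept.push_back(cand[taken[t]]);
  }
  for (size_t a = 0; a < kept.size(); ++a)
    for (size_t b = a + 1; b < kept.size(); ++b)
      if (kept[b].q_start < kept[a].q_start ||
          (kept[b].q_start == kept[a].q_start &&
           kept[b].s_start < kept[a].s_start)) {
        Extension t = kept[a]; kept[a] = kept[b]; kept[b] = t;
      }
  return kept;
}

// All query x subject pairs of a chunk pair in one call; each subject is
// word-indexed once. Returns hits with 1-based query/subject record
// indices alongside coordinates.
// [[Rcpp::export(name = ".cpp_search_chunk")]]
DataFrame cpp_search_chunk(CharacterVector queries, CharacterVector subjects,
                           int w, int match, int mismatch, int x_drop,
                           int min_raw_score) {
  std::vector<int> qi, si, qs, qe, ss, se, sc, mm, ln;
  for (int s = 0; s < subjects.size(); ++s) {
    std::string sub = as<std::string>(subjects[s]);
    WordIndex idx = index_words(sub, w);
    for (int q = 0; q < queries.size(); ++q) {
      std::string qry = as<std::string>(queries[q]);
      std::vector<Extension> kept = search_pair_core(
        qry, sub, idx, w, match, mismatch, x_drop, min_raw_score);
      for (size_t i = 0; i < kept.size(); ++i) {
        qi.push_back(q + 1); si.push_back(s + 1);
        qs.push_back(kept[i].q_start + 1); qe.push_back(kept[i].q_end + 1);
        ss.push_back(kept[i].s_start + 1); se.push_back(kept[i].s_end + 1);
        sc.push_back(kept[i].score); mm.push_back(kept[i].mismatches);
        ln.push_back(kept[i].length);
      }
    }
  }
  return DataFrame::create(
    _["query_index"] = wrap(qi), _["subject_index"] = wrap(si),
    _["q_start"] = wrap(qs), _["q_end"] = wrap(qe),
    _["s_start"] = wrap(ss), _["s_end"] = wrap(se),
    _["raw_score"] = wrap(sc), _["mismatches"] = wrap(mm),
    _["align_length"] = wrap(ln));
}

// All ungapped HSPs between one query and one subject: seed, extend,
// then per-diagonal resolution of overlapping extensions keeping the
// highest-scoring span (ties to the leftmost q_start).
// [[Rcpp::export(name = ".cpp_search_pair")]]
DataFrame cpp_search_pair(std::string query, std::string subject, int w,
                          int match, int mismatch, int x_drop,
                          int min_raw_score) {
  WordIndex idx = index_words(subject, w);
  std::vector<Extension> kept = search_pair_core(
    query, subject, idx, w, match, mismatch, x_drop, min_raw_score);
  int nh = (int)kept.size();
  IntegerVector qs(nh), qe(nh), ss(nh), se(nh), sc(nh), mm(nh), ln(nh);
  for (int i = 0; i < nh; ++i) {
    qs[i] = kept[i].q_start + 1; qe[i] = kept[i].q_end + 1;
    ss[i] = kept[i].s_start + 1; se[i] = kept[i].s_end + 1;
    sc[i] = kept[i].score; mm[i] = kept[i].mismatches;
    ln[i] = kept[i].length;
  }
  return DataFrame::create(
    _["q_start"] = qs, _["q_end"] = qe, _["s_start"] = ss, _["s_end"] = se,
    _["raw_score"] = sc, _["mismatches"] = mm, _["align_length"] = ln);
}
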