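// k-mer seeded banded Smith-Waterman, used for all-vs-all read comparison,
// read-vs-reference annotation, contaminant screening and transcript mapping.
// Scoring: match/mismatch are linear, a gap of length g costs open + g * ext
// (same convention as Biostrings::pairwiseAlignment gapOpening/gapExtension).

#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

static const int NEG_INF = -100000000;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4; // N / ambiguity: never matches
  }
}

static std::vector<uint8_t> encode(const std::string &s) {
  std::vector<uint8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = (uint8_t) base_code(s[i]);
  return v;
}

static std::vector<uint8_t> revcomp(const std::vector<uint8_t> &v) {
  std::vector<uint8_t> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    uint8_t c = v[v.size() - 1 - i];
    r[i] = c < 4 ? (uint8_t)(3 - c) : (uint8_t)4;
  }
  return r;
}

struct AlnResult {
  int score = 0;       // best local score
  int aln_len = 0;     // alignment columns (incl. gap columns)
  int n_match = 0;     // identical aligned bases
  bool ok = false;
};

// Reusable DP workspace: only band cells plus two sentinel columns per row
// are touched, so buffers are allocated once and never cleared in full.
struct AlnWork {
  std::vector<int> M, X, Y;
  std::vector<uint8_t> tbM, tbX, tbY;
  void ensure(size_t cells) {
    if (M.size() < cells) {
      M.resize(cells); X.resize(cells); Y.resize(cells);
      tbM.resize(cells); tbX.resize(cells); tbY.resize(cells);
    }
  }
};

// Banded local alignment of q against s restricted to diagonals
// (i - j) in [diag - band, diag + band], affine gaps, with traceback.
static AlnResult banded_sw(const std::vector<uint8_t> &q,
                           const std::vector<uint8_t> &s,
                           int diag, int band,
                           int match, int mismatch,
                           int gap_open, int gap_ext,
                           AlnWork &wk) {
  const int n = (int) q.size(), m = (int) s.size();
  const int W = 2 * band + 1;
  const int gape = gap_ext, gapo = gap_open + gap_ext; // cost of first gap base
  wk.ensure((size_t)n * W);
  int *M = wk.M.data(), *X = wk.X.data(), *Y = wk.Y.data();
  uint8_t *tbM = wk.tbM.data(), *tbX = wk.tbX.data(), *tbY = wk.tbY.data();
  int best = 0, bi = -1, bo = -1;
  int prev_olo = W, prev_ohi = -W; // valid offset range of the previous row
  for (int i = 0; i < n; ++i) {
    int jlo = std::max(0, i - diag - band);
    int jhi = std::min(m - 1, i - diag + band);
    if (jlo > jhi) { prev_olo = W; prev_ohi = -W; continue; }
    int olo = jlo - i + diag + band, ohi = jhi - i + diag + band;
    // sentinels just outside the valid offset range of this row
    if (olo - 1 >= 0) {
      size_t sidx = (size_t)i * W + (olo - 1);
      M[sidx] = X[sidx] = Y[sidx] = NEG_INF;
    }
    if (ohi + 1 < W) {
      size_t sidx = (size_t)i * W + (ohi + 1);
      M[sidx] = X[sidx] = Y[sidx] = NEG_INF;
    }
    for (int j = jlo; j <= jhi; ++j) {
      int o = j - i + diag + band;
      size_t idx = (size_t)i * W + o;
      // M: diagonal move, predecessor (i-1, j-1) has the same offset.
      // prev = 0 means "start a new local alignment here" (tb = 0).
      int sub = (q[i] < 4 && q[i] == s[j]) ? match : mismatch;
      int prev = 0;
      uint8_t tb = 0;
      if (i > 0 && j > 0 && o >= prev_olo - 1 && o <= prev_ohi + 1) {
        size_t pidx = (size_t)(i - 1) * W + o;
        if (M[pidx] > prev) { prev = M[pidx]; tb = 1; }
        if (X[pidx] > prev) { prev = X[pidx]; tb = 2; }
        if (Y[pidx] > prev) { prev = Y[pidx]; tb = 3; }
      }
      M[idx] = prev + sub; tbM[idx] = tb;
      // X: gap in subject (consume query), predecessor (i-1, j), offset o+1
      X[idx] = NEG_INF; tbX[idx] = 1;
      if (i > 0 && o + 1 < W && o + 1 >= prev_olo - 1 && o + 1 <= prev_ohi + 1) {
        size_t pidx = (size_t)(i - 1) * W + (o + 1);
        int fromM = M[pidx] > NEG_INF / 2 ? M[pidx] - gapo : NEG_INF;
        int fromX = X[pidx] > NEG_INF / 2 ? X[pidx] - gape : NEG_INF;
        if (fromM >= fromX) { X[idx] = fromM; tbX[idx] = 1; }
        else { X[idx] = fromX; tbX[idx] = 2; }
      }
      // Y: gap in query (consume subject), predecessor (i, j-1), offset o-1
      Y[idx] = NEG_INF; tbY[idx] = 1;
      if (j > 0 && o - 1 >= 0) {
        size_t pidx = (size_t)i * W + (o - 1);
        int fromM = M[pidx] > NEG_INF / 2 ? M[pidx] - gapo : NEG_INF;
        int fromY = Y[pidx] > NEG_INF / 2 ? Y[pidx] - gape : NEG_INF;
        if (fromM >= fromY) { Y[idx] = fromM; tbY[idx] = 1; }
        else { Y[idx] = fromY; tbY[idx] = 2; }
      }
      if (M[idx] > best) { best = M[idx]; bi = i; bo = o; }
    }
    prev_olo = olo; prev_ohi = ohi;
  }
  AlnResult res;
  if (best <= 0) return res;
  res.score = best; res.ok = true;
  // traceback from (bi, bo) through M
  int i = bi, o = bo, state = 0; // 0 = M, 1 = X, 2 = Y
  while (i >= 0) {
    size_t idx = (size_t)i * W + o;
    if (state == 0) {
      int j = i + o - diag - band;
      uint8_t c = (q[i] < 4 && j >= 0 && j < m && q[i] == s[j]) ? 1 : 0;
      res.aln_len += 1; res.n_match += c;
      uint8_t tb = tbM[idx];
      if (tb == 0) break;            // local start
      state = tb - 1;                // 0=M,1=X,2=Y
      i -= 1;                        // diagonal: i-1, same offset
      if (i < 0) break;
    } else if (state == 1) {
      res.aln_len += 1;              // query base vs gap
      uint8_t tb = tbX[idx];
      state = (tb == 1) ? 0 : 1;
      i -= 1; o += 1;
      if (i < 0 || o >= W) break;
    } else {
      res.aln_len += 1;              // gap vs subject base
      uint8_t tb = tbY[idx];
      state = (tb == 1) ? 0 : 2;
      o -= 1;
      if (o < 0) break;
    }
  }
  return res;
}

// Longest possible diagonal run for this (query, subject, diagonal); used to
// skip candidates that cannot reach the length/coverage thresholds.
static inline int diag_overlap(int n, int m, int d) {
  return std::min(n, m + d) - std::max(0, d);
}

// k-mer enumeration: 2-bit packed, windows containing N skipped.
static void kmers_of(const std::vector<uint8_t> &v, int k,
                     std::vector<std::pair<uint32_t, int> > &out) {
  out.clear();
  if ((int) v.size() < k) return;
  uint32_t key = 0, mask = (k < 16) ? ((1u << (2 * k)) - 1u) : 0xFFFFFFFFu;
  int run = 0;
  for (int i = 0; i < (int) v.size(); ++i) {
    if (v[i] > 3) { run = 0; key = 0; continue; }
    key = ((key << 2) | v[i]) & mask;
    if (++run >= k) out.push_back(std::make_pair(key, i - k + 1));
  }
}

struct Cand { int target; int strand; int diag; };

static bool cand_less(const Cand &a, const Cand &b) {
  if (a.target != b.target) return a.target < b.target;
  if (a.strand != b.strand) return a.strand < b.strand;
  return a.diag < b.diag;
}

// Pick the modal diagonal of a sorted run [lo, hi); ties prefer the smaller
// absolute diagonal (symmetric under query/subject swap), then the positive
// one.
static bool diag_better(int n, int d, int best_n, int best_d) {
  if (n != best_n) return n > best_n;
  if (std::abs(d) != std::abs(best_d)) return std::abs(d) < std::abs(best_d);
  return d > best_d;
}

static void mode_diag(const std::vector<Cand> &c, size_t lo, size_t hi,
                      int &diag, int &count) {
  int best_d = c[lo].diag, best_n = 0, cur_d = c[lo].diag, cur_n = 0;
  for (size_t t = lo; t < hi; ++t) {
    if (c[t].diag == cur_d) cur_n++;
    else {
      if (diag_better(cur_n, cur_d, best_n, best_d)) { best_n = cur_n; best_d = cur_d; }
      cur_d = c[t].diag; cur_n = 1;
    }
  }
  if (diag_better(cur_n, cur_d, best_n, best_d)) { best_n = cur_n; best_d = cur_d; }
  diag = best_d; count = (int)(hi - lo);
}

// [[Rcpp::export(name = ".cpp_all_vs_all_hits")]]
DataFrame cpp_all_vs_all_hits(CharacterVector seqs,
                              int k, int band, int min_seeds,
                              double min_len, double min_identity,
                              double min_coverage,
                              int match, int mismatch,
                              int gap_open, int gap_ext) {
  const int n = seqs.size();
  std::vector<std::vector<uint8_t> > fwd(n), rev(n);
  for (int i = 0; i < n; ++i) {
    fwd[i] = encode(as<std::string>(seqs[i]));
    rev[i] = revcomp(fwd[i]);
  }
  // index forward k-mers
  std::unordered_map<uint32_t, std::vector<std::pair<int, int> > > index;
  index.reserve((size_t)n * 8);
  std::vector<std::pair<uint32_t, int> > km;
  for (int i = 0; i < n; ++i) {
    kmers_of(fwd[i], k, km);
    for (size_t t = 0; t < km.size(); ++t)
      index[km[t].first].push_back(std::make_pair(i, km[t].second));
  }
  std::vector<int> out_q, out_s, out_score, out_len, out_strand;
  std::vector<double> out_id;
  std::vector<Cand> cands;
  AlnWork wk;
  for (int i = 1; i < n; ++i) {
    cands.clear();
    for (int strand = 0; strand < 2; ++strand) {
      const std::vector<uint8_t> &oq = strand ? rev[i] : fwd[i];
      kmers_of(oq, k, km);
      for (size_t t = 0; t < km.size(); ++t) {
        std::unordered_map<uint32_t, std::vector<std::pair<int, int> > >::const_iterator
          it = index.find(km[t].first);
        if (it == index.end()) continue;
        const std::vector<std::pair<int, int> > &v = it->second;
        for (size_t u = 0; u < v.size(); ++u) {
          if (v[u].first >= i) continue;
          Cand c; c.target = v[u].first; c.strand = strand;
          c.diag = km[t].second - v[u].second;
          cands.push_back(c);
        }
      }
    }
    if (cands.empty()) continue;
    std::sort(cands.begin(), cands.end(), cand_less);
    size_t lo = 0;
    // best hit per target across strands
    int cur_target = -1, cur_best_score = -1, cur_len = 0, cur_strand = 0;
    double cur_id = 0;
    for (size_t t = 1; t <= cands.size(); ++t) {
      bool flush = (t == cands.size()) ||
        cands[t].target != cands[lo].target || cands[t].strand != cands[lo].strand;
      if (!flush) continue;
      int diag, count;
      mode_diag(cands, lo, t, diag, count);
      int j = cands[lo].target, strand = cands[lo].strand;
      if (count >= min_seeds) {
        const std::vector<uint8_t> &oq = strand ? rev[i] : fwd[i];
        int shorter = (int) std::min(oq.size(), fwd[j].size());
        int reach = diag_overlap((int) oq.size(), (int) fwd[j].size(), diag) +
          band;
        if (reach < min_len || reach < min_coverage * shorter) { lo = t; continue; }
        AlnResult a = banded_sw(oq, fwd[j], diag, band, match, mismatch,
                                gap_open, gap_ext, wk);
        if (a.ok) {
          double iden = 100.0 * a.n_match / a.aln_len;
          double covr = (double) a.aln_len / (double) shorter;
          if (a.aln_len >= min_len && iden >= min_identity &&
              covr >= min_coverage) {
            if (cur_target != j) {
              if (cur_target >= 0) {
                out_q.push_back(i + 1); out_s.push_back(cur_target + 1);
                out_score.push_back(cur_best_score); out_len.push_back(cur_len);
                out_id.push_back(cur_id); out_strand.push_back(cur_strand);
              }
              cur_target = j; cur_best_score = a.score; cur_len = a.aln_len;
              cur_id = iden; cur_strand = strand ? -1 : 1;
            } else if (a.score > cur_best_score) {
              cur_best_score = a.score; cur_len = a.aln_len;
              cur_id = iden; cur_strand = strand ? -1 : 1;
            }
          }
        }
      }
      lo = t;
    }
    if (cur_target >= 0) {
      out_q.push_back(i + 1); out_s.push_back(cur_target + 1);
      out_score.push_back(cur_best_score); out_len.push_back(cur_len);
      out_id.push_back(cur_id); out_strand.push_back(cur_strand);
    }
  }
  return DataFrame::create(
    Named("query") = out_q, Named("subject") = out_s,
    Named("score") = out_score, Named("length") = out_len,
    Named("identity") = out_id, Named("strand") = out_strand);
}

// Reads (queries, both strands) against a set of reference sequences
// (forward-indexed). Emits the best qualifying hit per (read, reference).
// [[Rcpp::export(name = ".cpp_reads_vs_refs_hits")]]
DataFrame cpp_reads_vs_refs_hits(CharacterVector reads, CharacterVector refs,
                                 int k, int band, int min_seeds,
                                 double min_len, double min_identity,
                                 int match, int mismatch,
                                 int gap_open, int gap_ext) {
  const int n = reads.size(), m = refs.size();
  std::vector<std::vector<uint8_t> > ref_enc(m);
  std::unordered_map<uint32_t, std::vector<std::pair<int, int> > > index;
  std::vector<std::pair<uint32_t, int> > km;
  for (int j = 0; j < m; ++j) {
    ref_enc[j] = encode(as<std::string>(refs[j]));
    kmers_of(ref_enc[j], k, km);
    for (size_t t = 0; t < km.size(); ++t)
      index[km[t].first].push_back(std::make_pair(j, km[t].second));
  }
  std::vector<int> out_q, out_s, out_score, out_len, out_strand;
  std::vector<double> out_id;
  std::vector<Cand> cands;
  AlnWork wk;
  for (int i = 0; i < n; ++i) {
    std::vector<uint8_t> f = encode(as<std::string>(reads[i]));
    std::vector<uint8_t> r = revcomp(f);
    cands.clear();
    for (int strand = 0; strand < 2; ++strand) {
      const std::vector<uint8_t> &oq = strand ? r : f;
      kmers_of(oq, k, km);
      for (size_t t = 0; t < km.size(); ++t) {
        std::unordered_map<uint32_t, std::vector<std::pair<int, int> > >::const_iterator
          it = index.find(km[t].first);
        if (it == index.end()) continue;
        const std::vector<std::pair<int, int> > &v = it->second;
        for (size_t u = 0; u < v.size(); ++u) {
          Cand c; c.target = v[u].first; c.strand = strand;
          c.diag = km[t].second - v[u].second;
          cands.push_back(c);
        }
      }
    }
    if (cands.empty()) continue;
    std::sort(cands.begin(), cands.end(), cand_less);
    size_t lo = 0;
    int cur_target = -1, cur_best_score = -1, cur_len = 0, cur_strand = 0;
    double cur_id = 0;
    for (size_t t = 1; t <= cands.size(); ++t) {
      bool flush = (t == cands.size()) ||
        cands[t].target != cands[lo].target || cands[t].strand != cands[lo].strand;
      if (!flush) continue;
      int diag, count;
      mode_diag(cands, lo, t, diag, count);
      int j = cands[lo].target, strand = cands[lo].strand;
      if (count >= min_seeds) {
        const std::vector<uint8_t> &oq = strand ? r : f;
        int reach = diag_overlap((int) oq.size(), (int) ref_enc[j].size(),
                                 diag) + band;
        if (reach < min_len) { lo = t; continue; }
        AlnResult a = banded_sw(oq, ref_enc[j], diag, band, match, mismatch,
                                gap_open, gap_ext, wk);
        if (a.ok) {
          double iden = 100.0 * a.n_match / a.aln_len;
          if (a.aln_len >= min_len && iden >= min_identity) {
            if (cur_target != j) {
              if (cur_target >= 0) {
                out_q.push_back(i + 1); out_s.push_back(cur_target + 1);
                out_score.push_back(cur_best_score); out_len.push_back(cur_len);
                out_id.push_back(cur_id); out_strand.push_back(cur_strand);
              }
              cur_target = j; cur_best_score = a.score; cur_len = a.aln_len;
              cur_id = iden; cur_strand = strand ? -1 : 1;
            } else if (a.score > cur_best_score) {
              cur_best_score = a.score; cur_len = a.aln_len;
              cur_id = iden; cur_strand = strand ? -1 : 1;
            }
          }
        }
      }
      lo = t;
    }
    if (cur_target >= 0) {
      out_q.push_back(i + 1); out_s.push_back(cur_target + 1);
      out_score.push_back(cur_best_score); out_len.push_back(cur_len);
      out_id.push_back(cur_id); out_strand.push_back(cur_strand);
    }
  }
  return DataFrame::create(
    Named("query") = out_q, Named("subject") = out_s,
    Named("score") = out_score, Named("length") = out_len,
    Named("identity") = out_id, Named("strand") = out_strand);
}
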