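#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// Affine-gap banded local/global alignment kernels.
//
// Band geometry: cell (i, j) (1-based DP row over query, column over
// reference) is inside the band iff (j - i) - diag is in [-band, band],
// where diag is the anchoring diagonal (ref_pos - query_pos of a seed).
// With band >= qlen + rlen the banded recursion degenerates to the full
// matrix, so the same code serves both uses.
//
// Scores: match > 0, mismatch < 0; gap_open is the (positive) cost of the
// first gap column, gap_ext of each further column. gap_open == gap_ext
// gives a linear gap penalty.

static const int8_t ST_NONE = 0; // local-alignment start
static const int8_t ST_M = 1;
static const int8_t ST_IX = 2;   // gap in query (consumes reference)
static const int8_t ST_IY = 3;   // gap in reference (consumes query)

static const double NEG_INF = -1e18;

struct AlnResult {
  double score;
  int q_start, q_end, r_start, r_end; // 0-based half-open
  int matches, block_len;
  bool found;
};

// One banded affine DP pass with traceback. local == true: Smith-Waterman
// style (cells floor at 0, best cell anywhere); local == false: global over
// the full strings (Needleman-Wunsch with affine gaps inside the band).
static AlnResult band_align(const std::string &q, const std::string &r,
                            int diag, int band, bool local,
                            double match, double mismatch,
                            double gap_open, double gap_ext) {
  const int n = (int)q.size(), m = (int)r.size();
  const int W = 2 * band + 1;
  auto in_band = [&](int i, int j) {
    int d = (j - i) - diag;
    return d >= -band && d <= band;
  };
  auto col = [&](int i, int j) { return (j - i) - diag + band; };

  std::vector<double> M((size_t)(n + 1) * W, NEG_INF),
      IX((size_t)(n + 1) * W, NEG_INF), IY((size_t)(n + 1) * W, NEG_INF);
  std::vector<int8_t> PM((size_t)(n + 1) * W, ST_NONE),
      PX((size_t)(n + 1) * W, ST_NONE), PY((size_t)(n + 1) * W, ST_NONE);
  auto idx = [&](int i, int c) { return (size_t)i * W + c; };

  // global initialisation: row 0 / column 0 gap costs (inside band only)
  if (!local) {
    if (in_band(0, 0)) M[idx(0, col(0, 0))] = 0.0;
    for (int j = 1; j <= m; ++j)
      if (in_band(0, j)) {
        IX[idx(0, col(0, j))] = -gap_open - gap_ext * (j - 1);
        PX[idx(0, col(0, j))] = (j == 1) ? ST_M : ST_IX;
      }
    for (int i = 1; i <= n; ++i)
      if (in_band(i, 0)) {
        IY[idx(i, col(i, 0))] = -gap_open - gap_ext * (i - 1);
        PY[idx(i, col(i, 0))] = (i == 1) ? ST_M : ST_IY;
      }
  }

  double best = local ? 0.0 : NEG_INF;
  int bi = -1, bj = -1;
  int8_t bstate = ST_NONE;

  for (int i = 1; i <= n; ++i) {
    int jlo = std::max(1, i + diag - band), jhi = std::min(m, i + diag + band);
    for (int j = jlo; j <= jhi; ++j) {
      int c = col(i, j);
      // M: diagonal move
      double prevM = NEG_INF, prevX = NEG_INF, prevY = NEG_INF;
      if (in_band(i - 1, j - 1)) {
        size_t p = idx(i - 1, col(i - 1, j - 1));
        prevM = M[p]; prevX = IX[p]; prevY = IY[p];
      }
      double s = (q[i - 1] == r[j - 1]) ? match : mismatch;
      double base = std::max(prevM, std::max(prevX, prevY));
      int8_t from = ST_NONE;
      if (base == prevM && prevM > NEG_INF / 2) from = ST_M;
      else if (base == prevX && prevX > NEG_INF / 2) from = ST_IX;
      else if (base == prevY && prevY > NEG_INF / 2) from = ST_IY;
      double mval;
      if (local) {
        mval = std::max(0.0, base) + s;
        if (base <= 0.0) { mval = s; from = ST_NONE; }
        if (mval < 0.0 && s < 0.0) { /* keep; floor handled via best>=0 */ }
      } else {
        mval = (base > NEG_INF / 2) ? base + s : NEG_INF;
      }
      M[idx(i, c)] = mval;
      PM[idx(i, c)] = from;

      // IX: gap in query, consumes reference (move left)
      double xo = NEG_INF, xe = NEG_INF;
      if (in_band(i, j - 1)) {
        size_t p = idx(i, col(i, j - 1));
        xo = (M[p] > NEG_INF / 2) ? M[p] - gap_open : NEG_INF;
        xe = (IX[p] > NEG_INF / 2) ? IX[p] - gap_ext : NEG_INF;
      }
      if (xo >= xe) { IX[idx(i, c)] = xo; PX[idx(i, c)] = ST_M; }
      else          { IX[idx(i, c)] = xe; PX[idx(i, c)] = ST_IX; }

      // IY: gap in reference, consumes query (move up)
      double yo = NEG_INF, ye = NEG_INF;
      if (in_band(i - 1, j)) {
        size_t p = idx(i - 1, col(i - 1, j));
        yo = (M[p] > NEG_INF / 2) ? M[p] - gap_open : NEG_INF;
        ye = (IY[p] > NEG_INF / 2) ? IY[p] - gap_ext : NEG_INF;
      }
      if (yo >= ye) { IY[idx(i, c)] = yo; PY[idx(i, c)] = ST_M; }
      else          { IY[idx(i, c)] = ye; PY[idx(i, c)] = ST_IY; }

      if (local) {
        if (M[idx(i, c)] > best) { best = M[idx(i, c)]; bi = i; bj = j; bstate = ST_M; }
      }
    }
  }

  AlnResult res{0.0, 0, 0, 0, 0, 0, 0, false};
  if (!local) {
    if (!in_band(n, m)) return res;
    size_t p = idx(n, col(n, m));
    best = std::max(M[p], std::max(IX[p], IY[p]));
    if (best <= NEG_INF / 2) return res;
    bi = n; bj = m;
    bstate = (best == M[p]) ? ST_M : (best == IX[p] ? ST_IX : ST_IY);
  }
  if (bi < 0) return res; // empty local alignment

  // traceback
  int i = bi, j = bj, matches = 0, cols = 0;
  int8_t st = bstate;
  while (true) {
    if (!local && i == 0 && j == 0) break;
    size_t p = idx(i, col(i, j));
    if (st == ST_M) {
      int8_t from = PM[p];
      ++cols;
      if (q[i - 1] == r[j - 1]) ++matches;
      --i; --j;
      if (local && from == ST_NONE) break;
      st = from;
      if (!local && i == 0 && j == 0) break;
    } else if (st == ST_IX) {
      int8_t from = PX[p];
      ++cols; --j;
      st = from;
    } else if (st == ST_IY) {
      int8_t from = PY[p];
      ++cols; --i;
      st = from;
    } else {
      break;
    }
  }
  res.score = best;
  res.q_start = i; res.q_end = bi;
  res.r_start = j; res.r_end = bj;
  res.matches = matches; res.block_len = cols;
  res.found = true;
  return res;
}

static List aln_to_list(const AlnResult &a) {
  return List::create(_["score"] = a.score, _["q_start"] = a.q_start,
                      _["q_end"] = a.q_end, _["r_start"] = a.r_start,
                      _["r_end"] = a.r_end, _["matches"] = a.matches,
                      _["block_len"] = a.block_len, _["found"] = a.found);
}

// [[Rcpp::export]]
List cpp_align_banded(std::string query, std::string ref, int diag, int band,
                      bool local, double match, double mismatch,
                      double gap_open, double gap_ext) {
  if (band < 0) stop("band must be >= 0");
  AlnResult a = band_align(query, ref, diag, band, local, match, mismatch,
                           gap_open, gap_ext);
  return aln_to_list(a);
}

// Seed-chain extension: greedy thinning of co-linear exact seeds, banded
// global alignment of the inter-seed segments, and exact-match terminal
// extension. Unlike free local extension this cannot over-run a junction
// through chance matches: the ends grow only while bases agree exactly.
// [[Rcpp::export]]
List cpp_chain_extend(std::string q, std::string r, IntegerVector qpos,
                      IntegerVector rpos, int k, int band, double match,
                      double mismatch, double gap_open, double gap_ext) {
  int ns = qpos.size();
  if (ns == 0 || ns != rpos.size()) stop("bad seed vectors");
  std::vector<int> ord(ns);
  for (int i = 0; i < ns; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (qpos[a] != qpos[b]) return qpos[a] < qpos[b];
    return rpos[a] < rpos[b];
  });
  // bidirectional greedy co-linear thinning anchored at the seed closest
  // to the median diagonal; a spurious off-diagonal seed at either end
  // then cannot shift the chain (and hence the block edges)
  std::vector<long> diags(ns);
  for (int i = 0; i < ns; ++i) diags[i] = (long)rpos[ord[i]] - qpos[ord[i]];
  std::vector<long> ds = diags;
  std::nth_element(ds.begin(), ds.begin() + ns / 2, ds.end());
  long med = ds[ns / 2];
  int anchor = 0;
  for (int i = 1; i < ns; ++i)
    if (std::labs(diags[i] - med) < std::labs(diags[anchor] - med))
      anchor = i;
  std::vector<int> kq, kr;
  kq.push_back(qpos[ord[anchor]]);
  kr.push_back(rpos[ord[anchor]]);
  long last_q = kq[0], last_r = kr[0], last_d = diags[anchor];
  for (int oi = anchor + 1; oi < ns; ++oi) {
    int qp = qpos[ord[oi]], rp = rpos[ord[oi]];
    long d = (long)rp - qp;
    if (qp >= last_q + k && rp >= last_r + k && std::labs(d - last_d) <= band) {
      kq.push_back(qp); kr.push_back(rp);
      last_q = qp; last_r = rp; last_d = d;
    }
  }
  last_q = kq[0]; last_r = kr[0]; last_d = diags[anchor];
  std::vector<int> lq, lr;
  for (int oi = anchor - 1; oi >= 0; --oi) {
    int qp = qpos[ord[oi]], rp = rpos[ord[oi]];
    long d = (long)rp - qp;
    if (qp + k <= last_q && rp + k <= last_r && std::labs(d - last_d) <= band) {
      lq.push_back(qp); lr.push_back(rp);
      last_q = qp; last_r = rp; last_d = d;
    }
  }
  std::reverse(lq.begin(), lq.end());
  std::reverse(lr.begin(), lr.end());
  lq.insert(lq.end(), kq.begin(), kq.end());
  lr.insert(lr.end(), kr.begin(), kr.end());
  kq.swap(lq); kr.swap(lr);
  int nk = kq.size();
  long matches = (long)nk * k, cols = (long)nk * k;
  double score = (double)nk * k * match;
  for (int i = 0; i + 1 < nk; ++i) {
    int dq = kq[i + 1] - (kq[i] + k);
    int dr = kr[i + 1] - (kr[i] + k);
    if (dq == 0 && dr == 0) continue;
    if (dq == 0 || dr == 0) {
      int g = std::max(dq, dr);
      cols += g;
      score -= gap_open + gap_ext * (g - 1);
      continue;
    }
    AlnResult seg = band_align(q.substr(kq[i] + k, dq),
                               r.substr(kr[i] + k, dr), 0,
                               std::abs(dq - dr) + 8, false, match,
                               mismatch, gap_open, gap_ext);
    if (seg.found) {
      matches += seg.matches;
      cols += seg.block_len;
      score += seg.score;
    } else {
      cols += std::max(dq, dr);
      score += mismatch * std::max(dq, dr);
    }
  }
  // exact-match terminal extension
  int q_start = kq[0], r_start = kr[0];
  int q_end = kq[nk - 1] + k, r_end = kr[nk - 1] + k;
  while (q_start > 0 && r_start > 0 && q[q_start - 1] == r[r_start - 1]) {
    --q_start; --r_start; ++matches; ++cols; score += match;
  }
  while (q_end < (int)q.size() && r_end < (int)r.size() &&
         q[q_end] == r[r_end]) {
    ++q_end; ++r_end; ++matches; ++cols; score += match;
  }
  return List::create(_["score"] = score, _["q_start"] = q_start,
                      _["q_end"] = q_end, _["r_start"] = r_start,
                      _["r_end"] = r_end, _["matches"] = (int)matches,
                      _["block_len"] = (int)cols, _["found"] = true);
}

// Seed lookup against a reference index shared across many queries.
// [[Rcpp::export]]
List cpp_find_seeds_batch(std::vector<std::string> queries, std::string ref,
                          int k, int max_hits_per_kmer = 64) {
  if (k < 1) stop("k must be >= 1");
  std::unordered_multimap<std::string, int> index;
  if ((int)ref.size() >= k) {
    index.reserve(ref.size());
    for (int p = 0; p + k <= (int)ref.size(); ++p)
      index.emplace(ref.substr(p, k), p);
  }
  List out(queries.size());
  for (size_t qi = 0; qi < queries.size(); ++qi) {
    const std::string &query = queries[qi];
    std::vector<int> qs, rs;
    for (int p = 0; p + k <= (int)query.size(); ++p) {
      std::string kmer = query.substr(p, k);
      if (kmer.find_first_not_of("ACGT") != std::string::npos) continue;
      auto range = index.equal_range(kmer);
      int nh = 0;
      for (auto it = range.first; it != range.second; ++it) {
        if (++nh > max_hits_per_kmer) break;
        qs.push_back(p);
        rs.push_back(it->second);
      }
    }
    IntegerMatrix m(qs.size(), 2);
    for (size_t i = 0; i < qs.size(); ++i) {
      m(i, 0) = qs[i];
      m(i, 1) = rs[i];
    }
    out[qi] = m;
  }
  return out;
}

// All exact k-mer matches between query and reference, as a 2-column
// 0-based (qpos, rpos) matrix. Positions with non-ACGT characters never
// seed (they cannot match reliably anyway).
// [[Rcpp::export]]
IntegerMatrix cpp_find_seeds(std::string query, std::string ref, int k,
                             int max_hits_per_kmer = 64) {
  if (k < 1) stop("k must be >= 1");
  std::unordered_multimap<std::string, int> index;
  if ((int)ref.size() >= k) {
    index.reserve(ref.size());
    for (int p = 0; p + k <= (int)ref.size(); ++p)
      index.emplace(ref.substr(p, k), p);
  }
  std::vector<int> qs, rs;
  for (int p = 0; p + k <= (int)query.size(); ++p) {
    std::string kmer = query.substr(p, k);
    if (kmer.find_first_not_of("ACGT") != std::string::npos) continue;
    auto range = index.equal_range(kmer);
    int nh = 0;
    for (auto it = range.first; it != range.second; ++it) {
      if (++nh > max_hits_per_kmer) break;
      qs.push_back(p);
      rs.push_back(it->second);
    }
  }
  IntegerMatrix out(qs.size(), 2);
  for (size_t i = 0; i < qs.size(); ++i) {
    out(i, 0) = qs[i];
    out(i, 1) = rs[i];
  }
  return out;
}
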