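// Compiled core: nanopore-like error model, k-mer index over the doubled
// circular reference, gap-tolerant anchor chaining, base-level breakpoint
// refinement, banded edit distance, and pileup accumulation.
//
// All randomness comes from R's RNG (R::unif_rand) so set.seed() governs
// every simulated quantity.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

static inline int base2code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  }
  return -1;
}
static const char CODE2BASE[4] = {'A', 'C', 'G', 'T'};

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
    case 'A': c = 'T'; break;
    case 'C': c = 'G'; break;
    case 'G': c = 'C'; break;
    case 'T': c = 'A'; break;
    default: c = 'N';
    }
  }
  return r;
}

// [[Rcpp::export]]
std::string cpp_revcomp(const std::string& s) { return revcomp(s); }

// ---------------------------------------------------------------------------
// Error model
// ---------------------------------------------------------------------------

// Per base, independently: delete (rate boosted inside homopolymer runs of
// length >= hp_min), else possibly substitute (uniform over the 3 other
// bases); after each template base, insert a uniform random base with
// prob ins_rate.
// [[Rcpp::export]]
std::string cpp_apply_errors(const std::string& frag, double sub_rate,
                             double ins_rate, double del_rate, double hp_mult,
                             int hp_min) {
  int n = (int)frag.size();
  std::vector<bool> in_hp(n, false);
  int i = 0;
  while (i < n) {
    int j = i + 1;
    while (j < n && frag[j] == frag[i]) ++j;
    if (j - i >= hp_min)
      for (int t = i; t < j; ++t) in_hp[t] = true;
    i = j;
  }
  std::string out;
  out.reserve(n + (int)(n * (ins_rate + 0.01)) + 16);
  for (i = 0; i < n; ++i) {
    double dr = del_rate * (in_hp[i] ? hp_mult : 1.0);
    if (dr > 0.95) dr = 0.95;
    if (R::unif_rand() >= dr) {
      char c = frag[i];
      if (sub_rate > 0 && R::unif_rand() < sub_rate) {
        int code = base2code(c);
        int alt = (int)(R::unif_rand() * 3.0);
        if (alt > 2) alt = 2;
        if (code >= 0) {
          if (alt >= code) ++alt;
          c = CODE2BASE[alt];
        }
      }
      out.push_back(c);
    }
    if (ins_rate > 0 && R::unif_rand() < ins_rate)
      out.push_back(CODE2BASE[(int)(R::unif_rand() * 4.0) & 3]);
  }
  return out;
}

// ---------------------------------------------------------------------------
// K-mer index over the doubled reference
// ---------------------------------------------------------------------------

struct MtIndex {
  int L, k, max_occ;
  std::string ref2;  // reference concatenated with itself
  std::unordered_map<uint64_t, std::vector<int>> tab;  // 0-based starts in [0, L)
};

static bool kmer_code(const std::string& s, int pos, int k, uint64_t& out) {
  uint64_t v = 0;
  for (int t = 0; t < k; ++t) {
    int c = base2code(s[pos + t]);
    if (c < 0) return false;
    v = (v << 2) | (uint64_t)c;
  }
  out = v;
  return true;
}

// [[Rcpp::export]]
SEXP cpp_build_index(const std::string& seq, int k, int max_occ) {
  MtIndex* idx = new MtIndex();
  idx->L = (int)seq.size();
  idx->k = k;
  idx->max_occ = max_occ;
  idx->ref2 = seq + seq;
  for (int p = 0; p < idx->L; ++p) {
    uint64_t v;
    if (kmer_code(idx->ref2, p, k, v)) idx->tab[v].push_back(p);
  }
  for (auto it = idx->tab.begin(); it != idx->tab.end();) {
    if ((int)it->second.size() > max_occ)
      it = idx->tab.erase(it);
    else
      ++it;
  }
  XPtr<MtIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
IntegerVector cpp_lookup_kmer(SEXP xp, const std::string& kmer) {
  XPtr<MtIndex> idx(xp);
  if ((int)kmer.size() != idx->k) stop("k-mer length must equal index k");
  uint64_t v;
  if (!kmer_code(kmer, 0, idx->k, v)) return IntegerVector(0);
  auto it = idx->tab.find(v);
  if (it == idx->tab.end()) return IntegerVector(0);
  IntegerVector res(it->second.size());
  for (size_t t = 0; t < it->second.size(); ++t) res[t] = it->second[t] + 1;  // 1-based
  return res;
}

// ---------------------------------------------------------------------------
// Edit-distance machinery
// ---------------------------------------------------------------------------

// Edit distance of S against *prefixes* of T (semi-global, T-length free).
// bestD[i]  = min_j edit(S[0..i-1], T[0..j-1])
// bestLen[i]= the j achieving it; lenChoice 0 -> smallest such j, 1 -> largest.
static void prefix_edit(const std::string& S, const std::string& T,
                        int lenChoice, std::vector<int>& bestD,
                        std::vector<int>& bestLen) {
  int n = (int)S.size(), m = (int)T.size();
  bestD.assign(n + 1, 0);
  bestLen.assign(n + 1, 0);
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    int bd = cur[0], bl = 0;
    for (int j = 1; j <= m; ++j) {
      int d = prev[j - 1] + (S[i - 1] == T[j - 1] ? 0 : 1);
      if (prev[j] + 1 < d) d = prev[j] + 1;
      if (cur[j - 1] + 1 < d) d = cur[j - 1] + 1;
      cur[j] = d;
      if (d < bd || (d == bd && lenChoice == 1)) {
        bd = d;
        bl = j;
      }
    }
    bestD[i] = bd;
    bestLen[i] = bl;
    std::swap(prev, cur);
  }
}

// Banded local extension of S against T from their starts: +1 match, -2
// mismatch, -2 gap (log-phase scoring, so extension through random sequence
// drifts negative). Returns the (i, j) prefix pair with the maximum score;
// read ends that stop matching the reference (e.g. past an undetected
// junction) are soft-clipped instead of force-aligned.
static void extend_score(const std::string& S, const std::string& T, int band,
                         int& besti, int& bestj) {
  int n = (int)S.size(), m = (int)T.size();
  besti = 0;
  bestj = 0;
  if (n == 0 || m == 0) return;
  const int NEG = -(1 << 28);
  std::vector<int> prev(m + 1, NEG), cur(m + 1, NEG);
  int plo = 0, phi = std::min(m, band);
  for (int j = plo; j <= phi; ++j) prev[j] = -2 * j;
  int bestscore = 0;
  for (int i = 1; i <= n; ++i) {
    int lo = std::max(0, i - band), hi = std::min(m, i + band);
    for (int j = lo; j <= hi; ++j) {
      int v = NEG;
      if (j >= 1 && j - 1 >= plo && j - 1 <= phi && prev[j - 1] > NEG)
        v = prev[j - 1] + (S[i - 1] == T[j - 1] ? 1 : -2);
      if (j >= plo && j <= phi && prev[j] > NEG && prev[j] - 2 > v)
        v = prev[j] - 2;
      if (j - 1 >= lo && cur[j - 1] > NEG && cur[j - 1] - 2 > v)
        v = cur[j - 1] - 2;
      cur[j] = v;
      if (v > bestscore) {
        bestscore = v;
        besti = i;
        bestj = j;
      }
    }
    plo = lo;
    phi = hi;
    std::swap(prev, cur);
    std::fill(cur.begin(), cur.end(), NEG);
  }
}

// Banded global edit distance. Returns a large value when the band is blown.
static int band_edit(const std::string& A, const std::string& B, int extra) {
  int n = (int)A.size(), m = (int)B.size();
  if (n == 0) return m;
  if (m == 0) return n;
  int diff = m - n;
  int bl = std::max(8, (diff < 0 ? -diff : 0) + extra);
  int br = std::max(8, (diff > 0 ? diff : 0) + extra);
  const int INF = 1 << 28;
  std::vector<int> prev(m + 1, INF), cur(m + 1, INF);
  int plo = 0, phi = std::min(m, br);
  for (int j = plo; j <= phi; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    int lo = std::max(0, i - bl), hi = std::min(m, i + br);
    for (int j = lo; j <= hi; ++j) {
      int d = INF;
      if (j >= 1 && j - 1 >= plo && j - 1 <= phi && prev[j - 1] < INF)
        d = prev[j - 1] + (A[i - 1] == B[j - 1] ? 0 : 1);
      if (j >= plo && j <= phi && prev[j] < INF && prev[j] + 1 < d)
        d = prev[j] + 1;
      if (j - 1 >= lo && cur[j - 1] < INF && cur[j - 1] + 1 < d)
        d = cur[j - 1] + 1;
      cur[j] = d;
    }
    plo = lo;
    phi = hi;
    std::swap(prev, cur);
    std::fill(cur.begin(), cur.end(), INF);
  }
  if (m < plo || m > phi) return INF;
  return prev[m];
}

// [[Rcpp::export]]
int cpp_edit_distance(const std::string& a, const std::string& b, int extra) {
  int d = band_edit(a, b, extra);
  if (d >= (1 << 27)) d = band_edit(a, b, extra * 4 + 64);
  return d;
}

// ---------------------------------------------------------------------------
// Anchor chaining
// ---------------------------------------------------------------------------

struct ChainRes {
  std::vector<std::pair<int, int>> anchors;  // (q, r) 0-based, r on ref2
  double score = -1.0;
};

// anc must be sorted by (q, r). Longest-scoring co-linear chain; a reference
// gap g (|dr - dq|) between consecutive anchors costs gap_scale * log2(1+g),
// so multi-kb deletions stay cheap relative to the matched bases they join.
static ChainRes chain_core(const std::vector<std::pair<int, int>>& anc, int k,
                           double gap_scale, int max_ref_gap, int pred_window) {
  ChainRes res;
  int n = (int)anc.size();
  if (n == 0) return res;
  std::vector<double> f(n);
  std::vector<int> par(n, -1);
  double best = -1e18;
  int besti = -1;
  for (int i = 0; i < n; ++i) {
    f[i] = k;
    int j0 = std::max(0, i - pred_window);
    for (int j = j0; j < i; ++j) {  // ascending: leftmost predecessor wins ties
      int dq = anc[i].first - anc[j].first;
      int dr = anc[i].second - anc[j].second;
      if (dq <= 0 || dr <= 0) continue;
      if (dr - dq > max_ref_gap) continue;
      double upper = f[j] + std::min(k, dq);
      if (upper <= f[i] + 1e-9) continue;  // cannot improve even gap-free
      long g = (long)dr - (long)dq;
      if (g < 0) g = -g;
      double cand =
          g == 0 ? upper : upper - gap_scale * std::log2(1.0 + (double)g);
      if (cand > f[i] + 1e-9) {
        f[i] = cand;
        par[i] = j;
      }
    }
    if (f[i] > best + 1e-9 ||
        (besti >= 0 && std::fabs(f[i] - best) <= 1e-9 &&
         anc[i].second < anc[besti].second)) {
      best = f[i];
      besti = i;
    }
  }
  std::vector<int> path;
  for (int i = besti; i >= 0; i = par[i]) path.push_back(i);
  std::reverse(path.begin(), path.end());
  for (int i : path) res.anchors.push_back(anc[i]);
  res.score = best;
  return res;
}

// Exported for unit testing against a brute-force oracle.
// anchors: matrix with columns (read_pos, ref_pos), 1-based. Returns 1-based
// row indices of the selected chain.
// [[Rcpp::export]]
List cpp_chain_anchors(IntegerMatrix anchors, int k, double gap_scale,
                       int max_ref_gap, int pred_window) {
  int n = anchors.nrow();
  std::vector<std::pair<int, int>> anc(n);
  for (int i = 0; i < n; ++i)
    anc[i] = {anchors(i, 0) - 1, anchors(i, 1) - 1};
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (anc[a].first != anc[b].first) return anc[a].first < anc[b].first;
    return anc[a].second < anc[b].second;
  });
  std::vector<std::pair<int, int>> sorted(n);
  for (int i = 0; i < n; ++i) sorted[i] = anc[ord[i]];
  ChainRes cr = chain_core(sorted, k, gap_scale, max_ref_gap, pred_window);
  IntegerVector idx(cr.anchors.size());
  for (size_t t = 0; t < cr.anchors.size(); ++t) {
    // recover original row (first row matching the chained anchor)
    int found = -1;
    for (int i = 0; i < n && found < 0; ++i)
      if (anc[i] == cr.anchors[t]) found = i;
    idx[t] = found + 1;
  }
  return List::create(_["rows"] = idx, _["score"] = cr.score);
}

// ---------------------------------------------------------------------------
// Alignment of one read
// ---------------------------------------------------------------------------

struct Seg {
  int qs, qe, rs, re, ed;  // 0-based; r on ref2
};

static void collect_anchors(const MtIndex* idx, const std::string& read,
                            std::vector<std::pair<int, int>>& anc) {
  int k = idx->k, n = (int)read.size();
  for (int q = 0; q + k <= n; ++q) {
    uint64_t v;
    if (!kmer_code(read, q, k, v)) continue;
    auto it = idx->tab.find(v);
    if (it == idx->tab.end()) continue;
    for (int p : it->second) anc.push_back({q, p});
  }
}

static void subsample_anchors(std::vector<std::pair<int, int>>& anc,
                              int max_anchors) {
  int n = (int)anc.size();
  if (n <= max_anchors) return;
  int stride = (n + max_anchors - 1) / max_anchors;
  std::vector<std::pair<int, int>> out;
  out.reserve(n / stride + 1);
  for (int i = 0; i < n; i += stride) out.push_back(anc[i]);
  anc.swap(out);
}

// Refine one chain into segments with base-precise breakpoints.
static std::vector<Seg> refine_chain(const MtIndex* idx,
                                     const std::string& read,
                                     const std::vector<std::pair<int, int>>& ch,
                                     int window, int min_gap) {
  int k = idx->k;
  const std::string& ref2 = idx->ref2;
  int L2 = (int)ref2.size();
  int nread = (int)read.size();
  std::vector<Seg> segs;
  if (ch.empty()) return segs;

  // blocks of anchors separated by candidate junctions
  std::vector<std::array<int, 4>> blocks;  // qf, rf, ql, rl (anchor starts)
  int qf = ch[0].first, rf = ch[0].second;
  int ql = qf, rl = rf;
  for (size_t t = 1; t < ch.size(); ++t) {
    int dq = ch[t].first - ql, dr = ch[t].second - rl;
    if (dr - dq >= min_gap) {
      blocks.push_back({qf, rf, ql, rl});
      qf = ch[t].first;
      rf = ch[t].second;
    }
    ql = ch[t].first;
    rl = ch[t].second;
  }
  blocks.push_back({qf, rf, ql, rl});

  int nb = (int)blocks.size();
  // current open segment (read start, ref start)
  int cqs, crs;
  {  // head extension (local scoring; non-matching prefixes stay clipped)
    int q0 = blocks[0][0], r0 = blocks[0][1];
    cqs = q0;
    crs = r0;
    if (q0 > 0 && r0 > 0) {
      int tlen = std::min(q0 + window, r0);
      std::string P(read.rbegin() + (nread - q0), read.rend());  // read[0..q0-1] reversed
      std::string T(ref2.rbegin() + (L2 - r0), ref2.rbegin() + (L2 - r0) + tlen);
      int band = std::max(32, (int)(2.0 * std::sqrt((double)q0)));
      int bi, bj;
      extend_score(P, T, band, bi, bj);
      cqs = q0 - bi;
      crs = r0 - bj;
    }
  }

  for (int b = 0; b + 1 < nb; ++b) {
    int qa = blocks[b][2] + k - 1;   // last read base of left anchor
    int ra = blocks[b][3] + k - 1;   // last ref base matched
    int qb = blocks[b + 1][0];       // first read base of right anchor
    int rb = blocks[b + 1][1];       // first ref base of right anchor
    if (qb <= qa) {                  // anchors overlap in the read; shrink left
      int ov = qa - qb + 1;
      qa -= ov;
      ra -= ov;
    }
    // back off the flanking anchors so junctions inside direct repeats can
    // slide to their leftmost equivalent placement
    {
      int backL = std::min(2 * k, qa - blocks[b][0]);
      backL = std::min(backL, ra);
      if (backL > 0) { qa -= backL; ra -= backL; }
      int backR = std::min(2 * k, (blocks[b + 1][2] + k - 1) - qb);
      backR = std::min(backR, L2 - 1 - rb);
      if (backR > 0) { qb += backR; rb += backR; }
    }
    int m = qb - qa - 1;
    std::string S = read.substr(qa + 1, m);
    int llen = std::min(m + window, L2 - (ra + 1));
    if (llen < 0) llen = 0;
    std::string Lf = ref2.substr(ra + 1, llen);
    int rstart = rb - m - window;
    if (rstart < 0) rstart = 0;
    std::string Rf = ref2.substr(rstart, rb - rstart);
    std::vector<int> dl, ll, drv, lr;
    prefix_edit(S, Lf, 0, dl, ll);
    std::string Srev(S.rbegin(), S.rend());
    std::string Rrev(Rf.rbegin(), Rf.rend());
    prefix_edit(Srev, Rrev, 1, drv, lr);
    int besti = 0, bestc = (1 << 28), bestbp = (1 << 28);
    for (int i2 = 0; i2 <= m; ++i2) {
      int c = dl[i2] + drv[m - i2];
      int bp = ra + ll[i2];  // last ref base of left segment
      if (c < bestc || (c == bestc && bp < bestbp)) {
        bestc = c;
        besti = i2;
        bestbp = bp;
      }
    }
    int left_q_end = qa + besti;
    int left_r_end = ra + ll[besti];
    int right_q_start = left_q_end + 1;
    int right_r_start = rb - lr[m - besti];
    if (right_r_start - left_r_end - 1 <= 0) continue;  // junction vanished
    Seg s;
    s.qs = cqs;
    s.qe = left_q_end;
    s.rs = crs;
    s.re = left_r_end;
    s.ed = -1;
    segs.push_back(s);
    cqs = right_q_start;
    crs = right_r_start;
  }

  {  // tail extension (local scoring) and final segment
    int qe = blocks[nb - 1][2] + k - 1;
    int re = blocks[nb - 1][3] + k - 1;
    if (qe < nread - 1 && re < L2 - 1) {
      int slen = nread - 1 - qe;
      int tlen = std::min(slen + window, L2 - (re + 1));
      if (tlen < 0) tlen = 0;
      std::string S2 = read.substr(qe + 1, slen);
      std::string T2 = ref2.substr(re + 1, tlen);
      int band = std::max(32, (int)(2.0 * std::sqrt((double)slen)));
      int bi, bj;
      extend_score(S2, T2, band, bi, bj);
      qe = qe + bi;
      re = re + bj;
    }
    Seg s;
    s.qs = cqs;
    s.qe = qe;
    s.rs = crs;
    s.re = re;
    s.ed = -1;
    segs.push_back(s);
  }

  // per-segment edit distances
  for (auto& s : segs) {
    if (s.qe < s.qs || s.re < s.rs) {
      s.ed = std::max(0, s.qe - s.qs + 1) + std::max(0, s.re - s.rs + 1);
      continue;
    }
    std::string A = read.substr(s.qs, s.qe - s.qs + 1);
    std::string B = ref2.substr(s.rs, s.re - s.rs + 1);
    // indel imbalance along the optimal path grows ~sqrt(len); the wide-band
    // fallback inside cpp_edit_distance catches the rare blow-outs
    int extra = std::max(24, (int)(2.0 * std::sqrt((double)A.size())));
    s.ed = cpp_edit_distance(A, B, extra);
  }
  return segs;
}

struct OrientRes {
  double score = -1.0;
  std::vector<Seg> segs;
  int span = 0;  // read bases covered by the chain
};

static OrientRes align_orientation(const MtIndex* idx, const std::string& read,
                                   double gap_scale, int max_ref_gap,
                                   int pred_window, int refine_window,
                                   int min_gap, int max_anchors) {
  OrientRes out;
  std::vector<std::pair<int, int>> anc;
  collect_anchors(idx, read, anc);
  if (anc.empty()) return out;
  std::sort(anc.begin(), anc.end());
  subsample_anchors(anc, max_anchors);
  // duplicate every anchor one circle later so chains may cross the origin
  // (with or without deletion junctions); the leftmost tie-break keeps the
  // unlifted copy whenever both give the same chain
  {
    size_t n0 = anc.size();
    anc.reserve(2 * n0);
    for (size_t t = 0; t < n0; ++t)
      if (anc[t].second + idx->L + idx->k <= 2 * idx->L)  // stays inside ref2
        anc.push_back({anc[t].first, anc[t].second + idx->L});
    std::sort(anc.begin(), anc.end());
  }

  ChainRes best = chain_core(anc, idx->k, gap_scale, max_ref_gap, pred_window);
  int span = best.anchors.empty()
                 ? 0
                 : best.anchors.back().first - best.anchors.front().first +
                       idx->k;
  if (best.anchors.empty()) return out;
  // normalise ref offsets into [0, 2L)
  int rmin = best.anchors.front().second;
  if (rmin >= idx->L) {
    for (auto& a : best.anchors) a.second -= idx->L;
  }
  out.segs = refine_chain(idx, read, best.anchors, refine_window, min_gap);
  out.score = best.score;
  out.span = span;
  return out;
}

// [[Rcpp::export]]
List cpp_align_read(SEXP xp, const std::string& read, double gap_scale,
                    int max_ref_gap, int pred_window, int refine_window,
                    int min_gap, double min_cov_frac, int max_anchors) {
  XPtr<MtIndex> idx(xp);
  int n = (int)read.size();
  if (n < idx->k)
    return List::create(_["mapped"] = false, _["strand"] = "+",
                        _["score"] = 0.0,
                        _["segments"] = IntegerMatrix(0, 5));
  OrientRes fwd = align_orientation(idx.get(), read, gap_scale, max_ref_gap,
                                    pred_window, refine_window, min_gap,
                                    max_anchors);
  std::string rc = revcomp(read);
  OrientRes rev = align_orientation(idx.get(), rc, gap_scale, max_ref_gap,
                                    pred_window, refine_window, min_gap,
                                    max_anchors);
  bool use_rev = rev.score > fwd.score;
  OrientRes& best = use_rev ? rev : fwd;
  bool mapped = best.score > 0 && best.span >= min_cov_frac * n;
  IntegerMatrix segs((int)best.segs.size(), 5);
  for (int i = 0; i < (int)best.segs.size(); ++i) {
    segs(i, 0) = best.segs[i].qs + 1;  // 1-based read coords (oriented read)
    segs(i, 1) = best.segs[i].qe + 1;
    segs(i, 2) = best.segs[i].rs + 1;  // 1-based on doubled reference
    segs(i, 3) = best.segs[i].re + 1;
    segs(i, 4) = best.segs[i].ed;
  }
  return List::create(_["mapped"] = mapped,
                      _["strand"] = use_rev ? "-" : "+",
                      _["score"] = best.score, _["segments"] = segs);
}

// ---------------------------------------------------------------------------
// Pileup
// ---------------------------------------------------------------------------

// Banded global alignment with traceback; appends (ref offset within B,
// read base) for every column that consumes one read and one ref base.
static bool banded_traceback(const std::string& A, const std::string& B,
                             int extra, std::vector<int>& refoff,
                             std::vector<char>& rbase) {
  int n = (int)A.size(), m = (int)B.size();
  if (n == 0 || m == 0) return true;
  int diff = m - n;
  int bl = std::max(8, (diff < 0 ? -diff : 0) + extra);
  int br = std::max(8, (diff > 0 ? diff : 0) + extra);
  int width = bl + br + 1;
  const int INF = 1 << 28;
  std::vector<int> prev(m + 1, INF), cur(m + 1, INF);
  std::vector<uint8_t> dir((size_t)(n + 1) * width, 255);
  auto didx = [&](int i, int j) { return (size_t)i * width + (j - (i - bl)); };
  int plo = 0, phi = std::min(m, br);
  for (int j = plo; j <= phi; ++j) {
    prev[j] = j;
    if (j > 0) dir[didx(0, j)] = 2;
  }
  for (int i = 1; i <= n; ++i) {
    int lo = std::max(0, i - bl), hi = std::min(m, i + br);
    for (int j = lo; j <= hi; ++j) {
      int d = INF;
      uint8_t dd = 255;
      if (j >= 1 && j - 1 >= plo && j - 1 <= phi && prev[j - 1] < INF) {
        d = prev[j - 1] + (A[i - 1] == B[j - 1] ? 0 : 1);
        dd = 0;
      }
      if (j >= plo && j <= phi && prev[j] < INF && prev[j] + 1 < d) {
        d = prev[j] + 1;
        dd = 1;
      }
      if (j - 1 >= lo && cur[j - 1] < INF && cur[j - 1] + 1 < d) {
        d = cur[j - 1] + 1;
        dd = 2;
      }
      cur[j] = d;
      dir[didx(i, j)] = dd;
    }
    plo = lo;
    phi = hi;
    std::swap(prev, cur);
    std::fill(cur.begin(), cur.end(), INF);
  }
  if (m < plo || m > phi || prev[m] >= INF) return false;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int off = j - (i - bl);
    if (off < 0 || off >= width) return false;
    uint8_t dd = dir[(size_t)i * width + off];
    if (dd == 0) {
      refoff.push_back(j - 1);
      rbase.push_back(A[i - 1]);
      --i;
      --j;
    } else if (dd == 1) {
      --i;
    } else if (dd == 2) {
      --j;
    } else {
      return false;
    }
  }
  return true;
}

// counts: 4 x L integer matrix (rows A,C,G,T), updated in place.
// segs: columns (read_start, read_end, ref2_start, ref2_end), 1-based, for one
// oriented read.
// [[Rcpp::export]]
void cpp_pileup_add(IntegerMatrix counts, const std::string& ref2,
                    const std::string& read, IntegerMatrix segs, int L) {
  for (int srow = 0; srow < segs.nrow(); ++srow) {
    int qs = segs(srow, 0) - 1, qe = segs(srow, 1) - 1;
    int rs = segs(srow, 2) - 1, re = segs(srow, 3) - 1;
    if (qe < qs || re < rs) continue;
    std::string A = read.substr(qs, qe - qs + 1);
    std::string B = ref2.substr(rs, re - rs + 1);
    int extra = std::max(24, (int)(2.0 * std::sqrt((double)A.size())));
    std::vector<int> refoff;
    std::vector<char> rbase;
    if (!banded_traceback(A, B, extra, refoff, rbase)) {
      refoff.clear();
      rbase.clear();
      if (!banded_traceback(A, B, extra * 4 + 64, refoff, rbase)) continue;
    }
    for (size_t t = 0; t < refoff.size(); ++t) {
      int c = base2code(rbase[t]);
      if (c < 0) continue;
      counts(c, (rs + refoff[t]) % L) += 1;
    }
  }
}
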