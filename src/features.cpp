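// Hot per-sequence feature kernels. Sequences arrive as 1-based integer
// encodings over the 20-letter alphabet ACDEFGHIKLMNPQRSTVWY (R side does
// the encoding and all validation).
#include <Rcpp.h>
using namespace Rcpp;

// alphabet codes (1-based, alphabetical): D=3, E=4, K=9, P=13, Q=14, R=15
static inline bool is_pos(int a) { return a == 9 || a == 15; }
static inline bool is_neg(int a) { return a == 3 || a == 4; }

static double pat_delta(const std::vector<double>& fA,
                        const std::vector<double>& fB, int g) {
  int L = fA.size();
  int nw = L - g + 1;
  if (nw < 1) return NA_REAL;
  double sA = 0, sB = 0;
  for (int i = 0; i < L; ++i) { sA += fA[i]; sB += fB[i]; }
  double gA = sA / L, gB = sB / L;
  double denom = gA + gB;
  double glob = denom > 0 ? (gA - gB) * (gA - gB) / denom : 0.0;
  double wA = 0, wB = 0, acc = 0;
  for (int i = 0; i < g; ++i) { wA += fA[i]; wB += fB[i]; }
  for (int i = 0;; ++i) {
    double pA = wA / g, pB = wB / g, s = pA + pB;
    double sig = s > 0 ? (pA - pB) * (pA - pB) / s : 0.0;
    acc += (sig - glob) * (sig - glob);
    if (i + g >= L) break;
    wA += fA[i + g] - fA[i];
    wB += fB[i + g] - fB[i];
  }
  return acc / nw;
}

static double pat_ratio(const std::vector<double>& isA,
                        const std::vector<double>& isB, int g) {
  int L = isA.size();
  if (L < g) return NA_REAL;
  int nA = 0, nB = 0;
  for (int i = 0; i < L; ++i) { nA += isA[i] > 0; nB += isB[i] > 0; }
  std::vector<double> segA(L, 0.0), segB(L, 0.0);
  for (int i = 0; i < nA; ++i) segA[i] = 1.0;
  for (int i = L - nB; i < L; ++i) segB[i] = 1.0;
  double dmax = pat_delta(segA, segB, g);
  if (!(dmax > 0)) return NA_REAL;
  return pat_delta(isA, isB, g) / dmax;
}

// kappa / omega ratios at blob sizes 5 and 6: (k5, k6, o5, o6)
// [[Rcpp::export]]
NumericVector cpp_pat_bundle(IntegerVector idx) {
  int L = idx.size();
  NumericVector out(4, NA_REAL);
  std::vector<double> kA(L), kB(L), oA(L), oB(L);
  int nk = 0, no = 0;
  for (int i = 0; i < L; ++i) {
    int a = idx[i];
    kA[i] = is_pos(a); kB[i] = is_neg(a);
    oA[i] = (a == 13) || is_pos(a) || is_neg(a);
    oB[i] = 1.0 - oA[i];
    nk += kA[i] > 0 || kB[i] > 0;
    no += oA[i] > 0;
  }
  if (nk > 0) {
    out[0] = pat_ratio(kA, kB, 5);
    out[1] = pat_ratio(kA, kB, 6);
  }
  if (no > 0) {
    out[2] = pat_ratio(oA, oB, 5);
    out[3] = pat_ratio(oA, oB, 6);
  }
  return out;
}

// sequence charge decoration
// [[Rcpp::export]]
double cpp_scd(IntegerVector idx) {
  int L = idx.size();
  std::vector<int> pos;
  std::vector<double> q;
  for (int i = 0; i < L; ++i) {
    if (is_pos(idx[i])) { pos.push_back(i + 1); q.push_back(1.0); }
    else if (is_neg(idx[i])) { pos.push_back(i + 1); q.push_back(-1.0); }
  }
  int m = pos.size();
  if (m < 2) return 0.0;
  double tot = 0;
  for (int i = 0; i < m - 1; ++i)
    for (int j = i + 1; j < m; ++j)
      tot += q[i] * q[j] * std::sqrt((double)(pos[j] - pos[i]));
  return tot / L;
}

// minimum sliding-window Wootton-Federhen (entropy form, base 20)
// [[Rcpp::export]]
double cpp_cmin(IntegerVector idx, int w) {
  int L = idx.size();
  if (L < w) return NA_REAL;
  std::vector<double> term(w + 1, 0.0);
  double log20 = std::log(20.0);
  for (int n = 1; n <= w; ++n) {
    double p = (double)n / w;
    term[n] = -p * std::log(p) / log20;
  }
  std::vector<int> cnt(21, 0);
  double h = 0;
  for (int i = 0; i < w; ++i) cnt[idx[i]]++;
  for (int a = 1; a <= 20; ++a) h += term[cnt[a]];
  double hmin = h;
  for (int i = 0; i + w < L; ++i) {
    int out = idx[i], in = idx[i + w];
    if (out != in) {
      h -= term[cnt[out]] + term[cnt[in]];
      cnt[out]--; cnt[in]++;
      h += term[cnt[out]] + term[cnt[in]];
      if (h < hmin) hmin = h;
    }
  }
  return hmin;
}

// fraction of residues inside runs (>= min_run) of members; member flags
// are 0/1 over codes 1..20
// [[Rcpp::export]]
double cpp_run_frac(IntegerVector idx, LogicalVector member, int min_run) {
  int L = idx.size();
  int covered = 0, run = 0;
  for (int i = 0; i <= L; ++i) {
    bool in = (i < L) && member[idx[i] - 1];
    if (in) run++;
    else { if (run >= min_run) covered += run; run = 0; }
  }
  return (double)covered / L;
}

// count motif matches (overlapping, anchored at every start position);
// the motif is a residue-class pattern: one LogicalVector of length 20 per
// position (wildcards = all TRUE)
// [[Rcpp::export]]
double cpp_motif_count(IntegerVector idx, List flags) {
  int L = idx.size(), m = flags.size();
  if (m == 0 || L < m) return 0.0;
  std::vector<std::vector<int>> f(m);
  for (int k = 0; k < m; ++k) {
    LogicalVector fl = flags[k];
    f[k].assign(fl.begin(), fl.end());
  }
  int count = 0;
  for (int i = 0; i + m <= L; ++i) {
    bool ok = true;
    for (int k = 0; k < m; ++k)
      if (!f[k][idx[i + k] - 1]) { ok = false; break; }
    count += ok;
  }
  return (double)count;
}

// (longest member-run fraction, longest non-member-run fraction,
//  longest homopolymer-run fraction, mean homopolymer run length)
// [[Rcpp::export]]
NumericVector cpp_runstats(IntegerVector idx, LogicalVector member) {
  int L = idx.size();
  int run_in = 0, run_out = 0, best_in = 0, best_out = 0;
  int hrun = 0, hbest = 0, nruns = 0, cur = 0;
  for (int i = 0; i <= L; ++i) {
    bool in = (i < L) && member[idx[i] - 1];
    if (in) { run_in++; if (run_in > best_in) best_in = run_in; }
    else run_in = 0;
    if (i < L && !in) { run_out++; if (run_out > best_out) best_out = run_out; }
    else run_out = 0;
    int a = (i < L) ? idx[i] : 0;
    if (a == cur && a != 0) hrun++;
    else {
      if (cur != 0) { nruns++; if (hrun > hbest) hbest = hrun; }
      hrun = 1; cur = a;
    }
  }
  return NumericVector::create((double)best_in / L, (double)best_out / L,
                               (double)hbest / L, (double)L / nruns);
}
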