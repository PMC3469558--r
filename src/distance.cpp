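#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// 2-bit base encoding; -1 for anything outside A/C/G/T
static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// Code of the k-mer starting at each position (0-based), or -1 if the
// k-mer contains a non-ACGT character. Rolling computation, O(n).
// [[Rcpp::export]]
IntegerVector kmer_codes_cpp(std::string seq, int k) {
  int n = (int) seq.size();
  if (k < 1) stop("k must be >= 1");
  if (n < k) return IntegerVector(0);
  int np = n - k + 1;
  IntegerVector out(np);
  long long mask = (k >= 32) ? -1LL : ((1LL << (2 * k)) - 1);
  if (k > 15) stop("word length k > 15 is not supported");
  long long val = 0;
  int bad = 0; // positions since last invalid base
  // bad counts how many of the last k bases were invalid: track index of
  // the most recent invalid base instead.
  int last_bad = -1;
  for (int i = 0; i < n; i++) {
    int c = base_code(seq[i]);
    if (c < 0) { last_bad = i; c = 0; }
    val = ((val << 2) | c) & mask;
    int start = i - k + 1;
    if (start >= 0) out[start] = (last_bad >= start) ? -1 : (int) val;
  }
  (void) bad;
  return out;
}

// d[code] += delta, keeping S = sum(d^2) up to date
static inline void bump(std::vector<int> &d, long long &S, int code, int delta) {
  if (code < 0) return;
  int old = d[(size_t) code];
  d[(size_t) code] = old + delta;
  S += (long long) delta * (2LL * old + delta);
}

// Minimum windowed d2 between two sequences given their k-mer code arrays.
// Window of `window` bases = (window - k + 1) consecutive k-mer positions;
// a sequence shorter than the window is one whole-sequence window.
// Boustrophedon scan: every window move changes exactly two k-mer slots,
// so the squared-difference sum is maintained in O(1) per move. The diff
// buffer `d` must be all zero on entry and is restored to all zero on exit.
static long long d2_min_core(const IntegerVector &pc, const IntegerVector &qc,
                             int k, int window,
                             std::vector<int> &d) {
  int npk = pc.size(), nqk = qc.size(); // total k-mer positions
  int wk = window - k + 1;              // k-mer positions per full window
  int mp = std::min(wk, npk);           // k-mers per p window
  int mq = std::min(wk, nqk);
  int nwp = npk - mp + 1;               // number of window start positions
  int nwq = nqk - mq + 1;
  long long S = 0;
  for (int i = 0; i < mp; i++) bump(d, S, pc[i], +1);
  for (int j = 0; j < mq; j++) bump(d, S, qc[j], -1);
  long long best = S;
  int qs = 0, dir = +1;
  for (int ps = 0; ps < nwp; ps++) {
    if (ps > 0) { // slide p window by one base
      bump(d, S, pc[ps - 1], -1);
      bump(d, S, pc[ps - 1 + mp], +1);
      if (S < best) best = S;
    }
    // sweep q across its full range in the current direction
    if (dir > 0) {
      while (qs < nwq - 1) {
        bump(d, S, qc[qs], +1);
        bump(d, S, qc[qs + mq], -1);
        qs++;
        if (S < best) best = S;
      }
    } else {
      while (qs > 0) {
        bump(d, S, qc[qs + mq - 1], +1);
        bump(d, S, qc[qs - 1], -1);
        qs--;
        if (S < best) best = S;
      }
    }
    dir = -dir;
  }
  // restore buffer to zero for the next pair
  for (int i = nwp - 1; i < nwp - 1 + mp; i++) bump(d, S, pc[i], -1);
  for (int j = qs; j < qs + mq; j++) bump(d, S, qc[j], +1);
  return best;
}

// [[Rcpp::export]]
double d2_min_cpp(IntegerVector pcodes, IntegerVector qcodes, int k, int window) {
  if (pcodes.size() == 0 || qcodes.size() == 0)
    stop("sequence shorter than word length k: no words to compare");
  std::vector<int> d((size_t) 1 << (2 * k), 0);
  return (double) d2_min_core(pcodes, qcodes, k, window, d);
}

// Full pairwise raw d2 matrix; codes is a list of k-mer code vectors.
// If codes2 is supplied, entry (i,j) is d2 between codes[[i]] and codes2[[j]]
// (used for the reverse-complement option); otherwise the symmetric self
// matrix is computed.
// [[Rcpp::export]]
NumericMatrix d2_matrix_cpp(List codes, int k, int window,
                            Nullable<List> codes2 = R_NilValue) {
  int n = codes.size();
  NumericMatrix out(n, n);
  std::vector<int> d((size_t) 1 << (2 * k), 0);
  std::vector<IntegerVector> cv(n);
  for (int i = 0; i < n; i++) cv[i] = as<IntegerVector>(codes[i]);
  if (codes2.isNull()) {
    for (int i = 0; i < n; i++) {
      for (int j = i + 1; j < n; j++) {
        double v = (double) d2_min_core(cv[i], cv[j], k, window, d);
        out(i, j) = v;
        out(j, i) = v;
      }
      Rcpp::checkUserInterrupt();
    }
  } else {
    List c2(codes2);
    if (c2.size() != n) stop("codes2 must match codes in length");
    std::vector<IntegerVector> cv2(n);
    for (int i = 0; i < n; i++) cv2[i] = as<IntegerVector>(c2[i]);
    for (int i = 0; i < n; i++) {
      for (int j = i + 1; j < n; j++) {
        double v = (double) d2_min_core(cv[i], cv2[j], k, window, d);
        out(i, j) = v;
        out(j, i) = v;
      }
      Rcpp::checkUserInterrupt();
    }
  }
  return out;
}

// sparse (code, frequency) profile from a k-mer code vector
static void freq_profile(const IntegerVector &codes,
                         std::vector<int> &keys, std::vector<double> &freqs) {
  std::vector<int> valid;
  valid.reserve(codes.size());
  for (int i = 0; i < codes.size(); i++)
    if (codes[i] >= 0) valid.push_back(codes[i]);
  if (valid.empty()) stop("sequence contains no valid k-word");
  std::sort(valid.begin(), valid.end());
  double tot = (double) valid.size();
  keys.clear(); freqs.clear();
  size_t i = 0;
  while (i < valid.size()) {
    size_t j = i;
    while (j < valid.size() && valid[j] == valid[i]) j++;
    keys.push_back(valid[i]);
    freqs.push_back((double) (j - i) / tot);
    i = j;
  }
}

// base-2 Jensen-Shannon divergence between two sorted sparse profiles;
// 0 for identical profiles, 1 for disjoint supports
static double jsd2(const std::vector<int> &ka, const std::vector<double> &fa,
                   const std::vector<int> &kb, const std::vector<double> &fb) {
  const double LOG2 = std::log(2.0);
  double s = 0.0;
  size_t i = 0, j = 0;
  while (i < ka.size() || j < kb.size()) {
    double p = 0.0, q = 0.0;
    if (j >= kb.size() || (i < ka.size() && ka[i] < kb[j])) {
      p = fa[i++];
    } else if (i >= ka.size() || kb[j] < ka[i]) {
      q = fb[j++];
    } else {
      p = fa[i++]; q = fb[j++];
    }
    // per-word terms added in (hi, lo) order so the sum is exactly
    // symmetric in the two profiles
    double hi = p > q ? p : q, lo = p > q ? q : p;
    double m = 0.5 * (hi + lo);
    if (hi > 0) s += 0.5 * hi * std::log(hi / m) / LOG2;
    if (lo > 0) s += 0.5 * lo * std::log(lo / m) / LOG2;
  }
  if (s < 0) s = 0;
  if (s > 1) s = 1;
  return s;
}

// [[Rcpp::export]]
double gred_pair_cpp(IntegerVector pcodes, IntegerVector qcodes) {
  std::vector<int> ka, kb; std::vector<double> fa, fb;
  freq_profile(pcodes, ka, fa);
  freq_profile(qcodes, kb, fb);
  return jsd2(ka, fa, kb, fb);
}

// [[Rcpp::export]]
NumericMatrix gred_matrix_cpp(List codes, Nullable<List> codes2 = R_NilValue) {
  int n = codes.size();
  std::vector<std::vector<int> > keys(n);
  std::vector<std::vector<double> > freqs(n);
  for (int i = 0; i < n; i++) {
    IntegerVector c = as<IntegerVector>(codes[i]);
    freq_profile(c, keys[i], freqs[i]);
  }
  NumericMatrix out(n, n);
  if (codes2.isNull()) {
    for (int i = 0; i < n; i++)
      for (int j = i + 1; j < n; j++) {
        double v = jsd2(keys[i], freqs[i], keys[j], freqs[j]);
        out(i, j) = v; out(j, i) = v;
      }
  } else {
    List c2(codes2);
    if (c2.size() != n) stop("codes2 must match codes in length");
    std::vector<std::vector<int> > keys2(n);
    std::vector<std::vector<double> > freqs2(n);
    for (int i = 0; i < n; i++) {
      IntegerVector c = as<IntegerVector>(c2[i]);
      freq_profile(c, keys2[i], freqs2[i]);
    }
    for (int i = 0; i < n; i++)
      for (int j = i + 1; j < n; j++) {
        double v = jsd2(keys[i], freqs[i], keys2[j], freqs2[j]);
        out(i, j) = v; out(j, i) = v;
      }
  }
  return out;
}
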