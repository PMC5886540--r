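#include <Rcpp.h>
using namespace Rcpp;

// Circular-interval t-statistic scan.
//
// For an arc of length k starting at i (indices mod n), the statistic is
//   T = (mean(arc) - mean(complement)) / sqrt(1/k + 1/(n-k)).
// For fixed k, T is monotone in the arc sum, so per k only the max and min
// circular window sums are needed; each window length is scanned with a
// rolling sum, giving an O(n^2) total with a tiny constant.

struct ScanResult {
  double tmax;      // max |T|
  double tsigned;   // signed T at the arg max
  int i, j;         // 0-based inclusive arc [i..j], j < i means wrap
};

// tmax_only: |T| of an arc equals |T| of its complement, so scanning arc
// lengths up to n/2 suffices when only the maximum is needed (permutations).
static ScanResult scan_max_t(const double *x, int n, int min_width,
                             bool tmax_only = false) {
  ScanResult best;
  best.tmax = -1.0; best.tsigned = 0.0; best.i = -1; best.j = -1;
  if (n < 2 * min_width) return best;
  double stot = 0.0;
  for (int i = 0; i < n; ++i) stot += x[i];
  const int kmax = tmax_only ? n / 2 : n - min_width;
  for (int k = min_width; k <= kmax; ++k) {
    // rolling circular window sum of length k
    double s = 0.0;
    for (int i = 0; i < k; ++i) s += x[i];
    double smax = s, smin = s;
    int imax = 0, imin = 0;
    for (int i = 1; i < n; ++i) {
      s += x[(i + k - 1) % n] - x[i - 1];
      if (s > smax) { smax = s; imax = i; }
      if (s < smin) { smin = s; imin = i; }
    }
    const double q = 1.0 / k + 1.0 / (n - k);
    const double sq = std::sqrt(q);
    const double thi = (smax / k - (stot - smax) / (n - k)) / sq;
    const double tlo = (smin / k - (stot - smin) / (n - k)) / sq;
    // candidates in tie-break order (smaller start first)
    for (int c = 0; c < 2; ++c) {
      const int    ic = (c == 0) ? (imax <= imin ? imax : imin) : (imax <= imin ? imin : imax);
      const double tc = (c == 0) ? (imax <= imin ? thi : tlo)  : (imax <= imin ? tlo : thi);
      const double a = std::fabs(tc);
      const int jc = (ic + k - 1) % n;
      bool take = false;
      if (a > best.tmax) take = true;
      else if (a == best.tmax && best.i >= 0) {
        if (ic < best.i || (ic == best.i && jc < best.j)) take = true;
      }
      if (take) { best.tmax = a; best.tsigned = tc; best.i = ic; best.j = jc; }
    }
  }
  return best;
}

// [[Rcpp::export]]
List cbs_scan_cpp(NumericVector x, int min_width) {
  ScanResult r = scan_max_t(REAL(x), x.size(), min_width);
  return List::create(_["i"] = r.i, _["j"] = r.j,
                      _["t"] = r.tsigned, _["tmax"] = r.tmax);
}

// Fisher-Yates shuffle driven by R's RNG so set.seed() governs permutations.
static void shuffle_r(double *x, int n) {
  for (int i = n - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    double tmp = x[i]; x[i] = x[j]; x[j] = tmp;
  }
}

// T_max for each of nperm random permutations (full vector, for quantiles).
// [[Rcpp::export]]
NumericVector cbs_perm_tmax_cpp(NumericVector x, int min_width, int nperm) {
  const int n = x.size();
  std::vector<double> buf(REAL(x), REAL(x) + n);
  NumericVector out(nperm);
  RNGScope scope;
  for (int p = 0; p < nperm; ++p) {
    shuffle_r(buf.data(), n);
    ScanResult r = scan_max_t(buf.data(), n, min_width, true);
    out[p] = r.tmax < 0 ? 0.0 : r.tmax;
  }
  return out;
}

// Sequential permutation count: number of permutations with T_max >= t_obs,
// stopping early once the count exceeds max_exceed (significance is then
// ruled out). Returns c(exceedances, permutations_run).
// [[Rcpp::export]]
IntegerVector cbs_perm_count_cpp(NumericVector x, int min_width, int nperm,
                                 double t_obs, int max_exceed) {
  const int n = x.size();
  std::vector<double> buf(REAL(x), REAL(x) + n);
  int count = 0, used = 0;
  RNGScope scope;
  for (int p = 0; p < nperm; ++p) {
    shuffle_r(buf.data(), n);
    ScanResult r = scan_max_t(buf.data(), n, min_width, true);
    ++used;
    if (r.tmax >= t_obs) {
      ++count;
      if (max_exceed >= 0 && count > max_exceed) break;
    }
  }
  return IntegerVector::create(count, used);
}
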