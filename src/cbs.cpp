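#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Circular binary segmentation core: max mean-shift statistic over arcs.
//
// For a vector x[0..m-1], an arc is the index set (i, j] (0 <= i < j <= m);
// the statistic compares the arc mean against its complement's,
// standardized by the interval's overall variance:
//   T^2 = (mean_in - mean_out)^2 / (s^2 (1/k + 1/(m-k))).
// The variance term is constant across arcs (it cancels in the permutation
// reference), which is the standard CBS form: a within-group pooled
// variance would instead reward arcs trimmed to exclude extreme
// observations and over-segment flat regions.  For a fixed arc length k,
// |T| is monotone in |sum_in - k * mean|, so only the extreme windowed
// sums at each k need a full evaluation; the scan is O(m^2) cheap
// comparisons plus O(m) statistic evaluations.

static inline double t2_stat(double sum_in, double k, double m,
                             double tot, double s2) {
  double n_out = m - k;
  double d = sum_in / k - (tot - sum_in) / n_out;
  double denom = s2 * (1.0 / k + 1.0 / n_out);
  if (denom <= 0) {
    if (std::fabs(d) > 0)
      return std::numeric_limits<double>::infinity();
    return 0.0;
  }
  return d * d / denom;
}

// Returns (t2_max, i, j) for the best arc (i, j]; i, j are 0-based cut
// positions into x.  Ties resolved toward the first (smallest k, then
// smallest i) candidate examined.  A split of [0, m) into pieces of
// lengths i, k, m-i-k is admissible when every non-empty piece has at
// least min_width observations, i.e. i in {0} U [min_width, m-k-min_width]
// U {m-k}.
static void max_t_scan(const double *x, int m, int min_width,
                       double &best_t2, int &best_i, int &best_j) {
  best_t2 = -1.0; best_i = 0; best_j = m;
  if (m < 2 * min_width) return;
  std::vector<double> S(m + 1);
  S[0] = 0.0;
  double totsq = 0.0;
  for (int i = 0; i < m; ++i) {
    S[i + 1] = S[i] + x[i];
    totsq += x[i] * x[i];
  }
  double tot = S[m];
  double s2 = (totsq - tot * tot / m) / (m - 1.0);
  if (s2 < 0) s2 = 0; // numerical guard
  const double *Sp = S.data();
  for (int k = min_width; k <= m - min_width; ++k) {
    double smax = -std::numeric_limits<double>::infinity();
    double smin = std::numeric_limits<double>::infinity();
    int imax = -1, imin = -1;
    int last = m - k;
    auto scan_range = [&](int lo, int hi) {
      for (int i = lo; i <= hi; ++i) {
        double s = Sp[i + k] - Sp[i];
        if (s > smax) { smax = s; imax = i; }
        if (s < smin) { smin = s; imin = i; }
      }
    };
    scan_range(0, 0);
    if (last - min_width >= min_width)
      scan_range(min_width, last - min_width);
    if (last >= min_width) scan_range(last, last);
    if (imax < 0) continue;
    double t2a = t2_stat(smax, k, m, tot, s2);
    double t2b = t2_stat(smin, k, m, tot, s2);
    // examine the smaller-i candidate first so ties break deterministically
    int i1 = imax, i2 = imin;
    double v1 = t2a, v2 = t2b;
    if (i2 < i1) { std::swap(i1, i2); std::swap(v1, v2); }
    if (v1 > best_t2) { best_t2 = v1; best_i = i1; best_j = i1 + k; }
    if (v2 > best_t2) { best_t2 = v2; best_i = i2; best_j = i2 + k; }
  }
  if (best_t2 < 0) best_t2 = 0.0;
}

// [[Rcpp::export(name = ".cbs_max_t")]]
NumericVector cbs_max_t(NumericVector x, int min_width) {
  int m = x.size();
  double t2; int bi, bj;
  max_t_scan(REAL(x), m, min_width, t2, bi, bj);
  return NumericVector::create(t2, (double)bi, (double)bj);
}

// Permutation exceedance count for the observed max t^2.  Uses R's RNG
// (deterministic under set.seed); stops early once `max_exceed` permutations
// have reached the observed value, at which point the split is already
// rejected at the caller's alpha.
// [[Rcpp::export(name = ".cbs_perm_exceed")]]
IntegerVector cbs_perm_exceed(NumericVector x, double t2_obs, int n_perm,
                              int max_exceed, int min_width) {
  int m = x.size();
  std::vector<double> y(REAL(x), REAL(x) + m);
  int exceed = 0, done = 0;
  for (int p = 0; p < n_perm; ++p) {
    // Fisher-Yates shuffle driven by R's RNG
    for (int i = m - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(y[i], y[j]);
    }
    double t2; int bi, bj;
    max_t_scan(y.data(), m, min_width, t2, bi, bj);
    ++done;
    if (t2 >= t2_obs) {
      ++exceed;
      if (exceed >= max_exceed) break;
    }
  }
  return IntegerVector::create(exceed, done);
}
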