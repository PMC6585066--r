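#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Max absolute two-sample t statistic over arcs of the circularly joined
// sequence. An arc (i, j] (0 <= i < j <= n, local 1-based values i+1..j)
// is compared against its complement; the complement wraps around, so edge
// changepoints are covered by prefix/suffix arcs. Validity: arc length >= w,
// prefix i and suffix n-j each 0 or >= w, complement non-empty. The scan
// order (i ascending, then j) makes the reported argmax the lexicographically
// smallest pair among ties (replacement only on strictly larger |t|).
//
// t uses the pooled two-sample statistic computed from prefix sums; a zero
// pooled variance with unequal means maps to +Inf.
static double best_arc(const double *x, int n, int w,
                       int *best_i, int *best_j,
                       double stop_at /* early exit when reached; <=0: off */) {
  if (n < 2 * w) return 0.0;
  std::vector<double> C(n + 1);
  C[0] = 0.0;
  double Q = 0.0;
  for (int t = 0; t < n; ++t) {
    C[t + 1] = C[t] + x[t];
    Q += x[t] * x[t];
  }
  const double S = C[n];
  double tmax = 0.0;
  int bi = -1, bj = -1;
  for (int i = 0; i <= n - w; ++i) {
    if (i != 0 && i < w) continue;           // prefix must be 0 or >= w
    for (int j = i + w; j <= n; ++j) {
      int suf = n - j;
      if (suf != 0 && suf < w) continue;     // suffix must be 0 or >= w
      if (i == 0 && j == n) continue;        // complement empty
      int k = j - i, m = n - k;
      double m1 = (C[j] - C[i]) / k;
      double m2 = (S - (C[j] - C[i])) / m;
      double ss = Q - (double)k * m1 * m1 - (double)m * m2 * m2;
      if (ss < 0) ss = 0;
      double tt;
      if (n > 2) {
        double se = std::sqrt(ss / (n - 2) * (1.0 / k + 1.0 / m));
        double d = std::fabs(m1 - m2);
        tt = (se > 0) ? d / se : (d > 1e-12 ? R_PosInf : 0.0);
      } else {
        tt = 0.0;
      }
      if (tt > tmax) {
        tmax = tt; bi = i; bj = j;
        if (stop_at > 0 && tmax >= stop_at) {
          *best_i = bi; *best_j = bj;
          return tmax;
        }
      }
    }
  }
  *best_i = bi; *best_j = bj;
  return tmax;
}

// [[Rcpp::export]]
List cbs_best_arc_cpp(NumericVector x, int min_width) {
  int i = -1, j = -1;
  double t = best_arc(x.begin(), x.size(), min_width, &i, &j, -1.0);
  return List::create(_["i"] = i, _["j"] = j, _["t"] = t);
}

// Permutation exceedance count for the max-|t| statistic, with sequential
// early stopping on the non-significant side: once `exceed` reaches
// `stop_count` the p-value is guaranteed to exceed alpha, so later draws
// cannot change the accept/reject decision. Uses the R RNG (deterministic
// under set.seed upstream).
// [[Rcpp::export]]
List cbs_perm_test_cpp(NumericVector x, double t_obs, int min_width,
                       int n_perm, int stop_count) {
  int n = x.size();
  std::vector<double> y(x.begin(), x.end());
  int exceed = 0, done = 0;
  for (int b = 0; b < n_perm; ++b) {
    // Fisher-Yates shuffle driven by R's RNG
    for (int t = n - 1; t > 0; --t) {
      int k = (int)std::floor(unif_rand() * (t + 1));
      if (k > t) k = t;
      std::swap(y[t], y[k]);
    }
    int i, j;
    double tp = best_arc(y.data(), n, min_width, &i, &j, t_obs);
    ++done;
    if (tp >= t_obs) {
      if (++exceed >= stop_count) break;
    }
  }
  return List::create(_["exceed"] = exceed, _["n_done"] = done);
}
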