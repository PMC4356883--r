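#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Best standard-deviation-reduction split over all columns of X.
//
// For each column, NA cells are imputed with the column mean computed on the
// rows of this node only; candidate thresholds are midpoints between
// consecutive distinct sorted values; both children must hold at least
// min_instances rows.  Score = sd(parent) - sum_i (n_i/n) * sd(child_i),
// with population (denominator n) standard deviations.
//
// Ties are broken deterministically: lowest column index first, then smallest
// threshold (strict > comparisons while scanning columns and thresholds in
// ascending order).  Returns col = 0 when no split with positive score exists.
// [[Rcpp::export]]
List scan_best_split_cpp(NumericMatrix X, NumericVector y, int min_instances) {
  const int n = X.nrow(), p = X.ncol();
  int best_col = -1;
  double best_thr = NA_REAL, best_score = -1.0;

  if (n < 2 * min_instances || n < 2)
    return List::create(_["col"] = 0, _["threshold"] = NA_REAL, _["score"] = NA_REAL);

  double s = 0.0, s2 = 0.0;
  for (int i = 0; i < n; ++i) { s += y[i]; s2 += y[i] * y[i]; }
  const double mean = s / n;
  double var_p = s2 / n - mean * mean;
  if (var_p < 0) var_p = 0;
  const double sd_p = std::sqrt(var_p);

  std::vector<double> xv(n), cy(n), cy2(n);
  std::vector<int> ord(n);

  for (int j = 0; j < p; ++j) {
    double cs = 0.0; int cn = 0;
    for (int i = 0; i < n; ++i) {
      double v = X(i, j);
      if (!ISNAN(v)) { cs += v; ++cn; }
    }
    if (cn == 0) continue;  // all missing in this node: column unusable
    const double cmean = cs / cn;
    for (int i = 0; i < n; ++i) {
      double v = X(i, j);
      xv[i] = ISNAN(v) ? cmean : v;
      ord[i] = i;
    }
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return xv[a] < xv[b]; });

    double ay = 0.0, ay2 = 0.0;
    for (int i = 0; i < n; ++i) {
      const double yi = y[ord[i]];
      ay += yi; ay2 += yi * yi;
      cy[i] = ay; cy2[i] = ay2;
    }

    for (int i = min_instances - 1; i <= n - min_instances - 1; ++i) {
      const double xl = xv[ord[i]], xr = xv[ord[i + 1]];
      if (xr <= xl) continue;
      const int nl = i + 1, nr = n - nl;
      const double ml = cy[i] / nl;
      double vl = cy2[i] / nl - ml * ml; if (vl < 0) vl = 0;
      const double mr = (s - cy[i]) / nr;
      double vr = (s2 - cy2[i]) / nr - mr * mr; if (vr < 0) vr = 0;
      const double score = sd_p
        - (static_cast<double>(nl) / n) * std::sqrt(vl)
        - (static_cast<double>(nr) / n) * std::sqrt(vr);
      if (score > best_score) {
        best_score = score;
        best_col = j;
        best_thr = (xl + xr) / 2.0;
      }
    }
  }

  if (best_col < 0 || best_score <= 1e-12)
    return List::create(_["col"] = 0, _["threshold"] = NA_REAL, _["score"] = NA_REAL);
  return List::create(_["col"] = best_col + 1, _["threshold"] = best_thr,
                      _["score"] = best_score);
}
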