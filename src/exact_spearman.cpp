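#include <Rcpp.h>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Exact permutation p-value for Spearman's rank correlation with midranks.
// Enumerates every distinct arrangement of the y-ranks (std::next_permutation
// over the sorted multiset, which weights tied arrangements correctly) and
// returns the two-sided tail probability P(|r_perm| >= |r_obs|).
// Feasible for n <= 10 (10! = 3,628,800 arrangements).
// [[Rcpp::export]]
double exact_spearman_pvalue(NumericVector xr, NumericVector yr) {
  const int n = xr.size();
  if (n != yr.size()) stop("rank vectors must have equal length");
  if (n < 2) stop("need at least two observations");
  if (n > 10) stop("exact permutation p-value is limited to n <= 10");

  double mx = 0.0, my = 0.0;
  for (int i = 0; i < n; ++i) { mx += xr[i]; my += yr[i]; }
  mx /= n; my /= n;
  double sxx = 0.0, syy = 0.0, sxy_obs = 0.0;
  for (int i = 0; i < n; ++i) {
    sxx += (xr[i] - mx) * (xr[i] - mx);
    syy += (yr[i] - my) * (yr[i] - my);
    sxy_obs += xr[i] * yr[i];
  }
  if (sxx <= 0.0 || syy <= 0.0) stop("constant ranks: correlation undefined");
  const double denom = std::sqrt(sxx * syy);
  const double shift = n * mx * my;
  const double r_obs = std::fabs((sxy_obs - shift) / denom);
  const double tol = 1e-12;

  std::vector<double> y(yr.begin(), yr.end());
  std::sort(y.begin(), y.end());
  double hits = 0.0, total = 0.0;
  do {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += xr[i] * y[i];
    const double r = std::fabs((s - shift) / denom);
    if (r >= r_obs - tol) hits += 1.0;
    total += 1.0;
  } while (std::next_permutation(y.begin(), y.end()));
  return hits / total;
}
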