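#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Multivariate DTW with Euclidean (not squared) point distance,
// step pattern {(1,0),(0,1),(1,1)}, fixed endpoints. Returns the minimal
// cumulative distance and one optimal warping path (1-based index pairs).
// Traceback prefers the diagonal step on ties, then (i-1,j), then (i,j-1),
// so the returned path is deterministic.
// [[Rcpp::export(name = ".dtw_core")]]
List dtw_core(NumericMatrix X, NumericMatrix Y) {
  const int n = X.nrow(), m = Y.nrow(), c = X.ncol();
  if (Y.ncol() != c) stop("channel count mismatch");
  if (n < 1 || m < 1) stop("empty series");

  NumericMatrix D(n + 1, m + 1);
  const double inf = std::numeric_limits<double>::infinity();
  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) D(i, j) = inf;
  D(0, 0) = 0.0;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double d = 0.0;
      for (int k = 0; k < c; ++k) {
        double diff = X(i - 1, k) - Y(j - 1, k);
        d += diff * diff;
      }
      d = std::sqrt(d);
      double best = D(i - 1, j - 1);
      if (D(i - 1, j) < best) best = D(i - 1, j);
      if (D(i, j - 1) < best) best = D(i, j - 1);
      D(i, j) = d + best;
    }
  }

  // traceback
  std::vector<int> pi, pj;
  int i = n, j = m;
  pi.push_back(i); pj.push_back(j);
  while (i > 1 || j > 1) {
    double diag = (i > 1 && j > 1) ? D(i - 1, j - 1) : inf;
    double up   = (i > 1) ? D(i - 1, j) : inf;
    double left = (j > 1) ? D(i, j - 1) : inf;
    if (diag <= up && diag <= left) { --i; --j; }
    else if (up <= left)            { --i; }
    else                            { --j; }
    pi.push_back(i); pj.push_back(j);
  }
  const int L = pi.size();
  IntegerMatrix path(L, 2);
  for (int k = 0; k < L; ++k) {
    path(k, 0) = pi[L - 1 - k];
    path(k, 1) = pj[L - 1 - k];
  }
  return List::create(_["distance"] = D(n, m), _["path"] = path);
}

// Average all X samples mapped to each template index q along a warping
// path; output has exactly the template length. Template indices repeated
// against one X sample replicate that sample.
// [[Rcpp::export(name = ".warp_average_core")]]
NumericMatrix warp_average_core(NumericMatrix X, IntegerMatrix path,
                                int t_template) {
  const int c = X.ncol(), L = path.nrow();
  NumericMatrix out(t_template, c);
  std::vector<int> counts(t_template, 0);
  for (int k = 0; k < L; ++k) {
    int p = path(k, 0) - 1, q = path(k, 1) - 1;
    for (int ch = 0; ch < c; ++ch) out(q, ch) += X(p, ch);
    counts[q]++;
  }
  for (int q = 0; q < t_template; ++q) {
    if (counts[q] == 0) stop("warping path does not cover template index");
    for (int ch = 0; ch < c; ++ch) out(q, ch) /= counts[q];
  }
  return out;
}
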