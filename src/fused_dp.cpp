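#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Exact minimizer of
//     sum_i w_i (y_i - b_i)^2  +  lam * sum_{i>1} |b_i - b_{i-1}|
// for strictly positive weights w, by forward dynamic programming over
// piecewise-quadratic messages followed by backtracking.  The derivative of
// each message is a continuous, nondecreasing piecewise-linear function kept
// as a deque of knots with (slope, intercept) increments; each forward step
// clips it to [-lam, lam] and adds the next data term.  Amortized O(n).
//
// Long-double accumulators matter: the +lam / -lam contributions entering
// the intercepts cancel only inexactly in double precision, which at
// lam ~ 1e9 would leave O(1e-7) errors in the fitted values.

// [[Rcpp::export]]
NumericVector fused_dp_weighted(NumericVector y, NumericVector w, double lam) {
  const int n = y.size();
  NumericVector beta(n);
  if (n == 0) return beta;
  if (n == 1 || lam <= 0.0) {
    for (int i = 0; i < n; ++i) beta[i] = y[i];
    return beta;
  }

  std::vector<long double> x(2 * n), a(2 * n), b(2 * n);
  std::vector<double> tm(n - 1), tp(n - 1);

  // message for site 0, clipped, then data term of site 1 added
  int l = n - 1, r = n;
  tm[0] = y[0] - lam / (2.0 * w[0]);
  tp[0] = y[0] + lam / (2.0 * w[0]);
  x[l] = tm[0];
  x[r] = tp[0];
  a[l] = 2.0L * w[0];
  b[l] = -2.0L * w[0] * y[0] + lam;
  a[r] = -2.0L * w[0];
  b[r] = 2.0L * w[0] * y[0] + lam;
  long double afirst = 2.0L * w[1], bfirst = -2.0L * w[1] * y[1] - lam;
  long double alast = 2.0L * w[1], blast = -2.0L * w[1] * y[1] + lam;

  for (int k = 2; k < n; ++k) {
    // clip: locate where the derivative crosses -lam ...
    long double alo = afirst, blo = bfirst;
    int lo = l;
    while (lo <= r && alo * x[lo] + blo < -lam) {
      alo += a[lo];
      blo += b[lo];
      ++lo;
    }
    const long double bm = (-lam - blo) / alo;

    // ... and +lam
    long double ahi = alast, bhi = blast;
    int hi = r;
    while (hi >= l && ahi * x[hi] + bhi > lam) {
      ahi -= a[hi];
      bhi -= b[hi];
      --hi;
    }
    const long double bp = (lam - bhi) / ahi;

    tm[k - 1] = (double)bm;
    tp[k - 1] = (double)bp;

    // surviving interior pieces are x[lo..hi]; insert clip knots and the
    // new data term (the data term lives in afirst/alast, the increments
    // at the clip knots restore the interior coefficients)
    l = lo - 1;
    x[l] = bm;
    a[l] = alo;
    b[l] = blo + lam;
    r = hi + 1;
    x[r] = bp;
    a[r] = -ahi;
    b[r] = -bhi + lam;
    afirst = 2.0L * w[k];
    bfirst = -2.0L * w[k] * y[k] - lam;
    alast = 2.0L * w[k];
    blast = -2.0L * w[k] * y[k] + lam;
  }

  // minimize the final message: derivative root
  long double alo = afirst, blo = bfirst;
  int lo = l;
  while (lo <= r && alo * x[lo] + blo < 0.0L) {
    alo += a[lo];
    blo += b[lo];
    ++lo;
  }
  beta[n - 1] = (double)(-blo / alo);

  for (int k = n - 2; k >= 0; --k) {
    if (beta[k + 1] > tp[k])
      beta[k] = tp[k];
    else if (beta[k + 1] < tm[k])
      beta[k] = tm[k];
    else
      beta[k] = beta[k + 1];
  }
  return beta;
}
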