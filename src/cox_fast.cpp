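#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Univariate Cox partial-likelihood fit by Newton-Raphson, Efron ties.
// Returns c(beta, se, z, loglik, converged). Independent of survival::coxph;
// used as the fast engine in resampling loops and as a cross-check elsewhere.
// [[Rcpp::export(name = ".cox_uni_fast")]]
NumericVector cox_uni_fast(NumericVector x, NumericVector time,
                           IntegerVector status, int max_iter = 30,
                           double tol = 1e-9) {
  const int n = x.size();
  if (time.size() != n || status.size() != n)
    stop("x, time and status must have equal length");

  // order by time ascending
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (time[a] != time[b]) return time[a] < time[b];
    return status[a] > status[b];
  });
  std::vector<double> tt(n), xx(n);
  std::vector<int> ev(n);
  for (int i = 0; i < n; ++i) {
    tt[i] = time[ord[i]];
    xx[i] = x[ord[i]];
    ev[i] = status[ord[i]];
  }

  double beta = 0.0, loglik_prev = R_NegInf, loglik = 0.0;
  bool converged = false;

  for (int iter = 0; iter < max_iter; ++iter) {
    // accumulate from largest time downwards
    double S0 = 0.0, S1 = 0.0, S2 = 0.0;
    double U = 0.0, I = 0.0;
    loglik = 0.0;
    int i = n - 1;
    while (i >= 0) {
      int j = i;
      // block of tied times
      while (j >= 0 && tt[j] == tt[i]) --j;
      // add whole tied block to the risk set
      double d0 = 0.0, d1 = 0.0, d2 = 0.0, sx = 0.0;
      int d = 0;
      for (int k = i; k > j; --k) {
        double r = std::exp(beta * xx[k]);
        S0 += r;
        S1 += r * xx[k];
        S2 += r * xx[k] * xx[k];
        if (ev[k]) {
          d0 += r; d1 += r * xx[k]; d2 += r * xx[k] * xx[k];
          sx += xx[k];
          ++d;
        }
      }
      if (d > 0) {
        loglik += beta * sx;
        U += sx;
        for (int l = 0; l < d; ++l) {
          double f = (double)l / d;
          double den = S0 - f * d0;
          double m1 = (S1 - f * d1) / den;
          double m2 = (S2 - f * d2) / den;
          loglik -= std::log(den);
          U -= m1;
          I += m2 - m1 * m1;
        }
      }
      i = j;
    }
    if (I <= 0.0) break;
    // the univariate partial likelihood is concave; clamped Newton suffices
    double step = U / I;
    if (step > 2.0) step = 2.0;
    if (step < -2.0) step = -2.0;
    beta += step;
    if (std::abs(step) < tol) converged = true;
    loglik_prev = loglik;
    if (converged) break;
    if (std::abs(beta) > 25.0) break;  // monotone likelihood / separation
  }

  // final information for the SE at the converged beta
  double S0 = 0.0, S1 = 0.0, S2 = 0.0, I = 0.0;
  int i = n - 1;
  while (i >= 0) {
    int j = i;
    while (j >= 0 && tt[j] == tt[i]) --j;
    double d0 = 0.0, d1 = 0.0, d2 = 0.0;
    int d = 0;
    for (int k = i; k > j; --k) {
      double r = std::exp(beta * xx[k]);
      S0 += r; S1 += r * xx[k]; S2 += r * xx[k] * xx[k];
      if (ev[k]) { d0 += r; d1 += r * xx[k]; d2 += r * xx[k] * xx[k]; ++d; }
    }
    for (int l = 0; l < d; ++l) {
      double f = (double)l / d;
      double den = S0 - f * d0;
      double m1 = (S1 - f * d1) / den;
      double m2 = (S2 - f * d2) / den;
      I += m2 - m1 * m1;
    }
    i = j;
  }
  double se = (I > 0.0) ? 1.0 / std::sqrt(I) : NA_REAL;
  double z = R_finite(se) && se > 0 ? beta / se : NA_REAL;
  return NumericVector::create(beta, se, z, loglik,
                               converged ? 1.0 : 0.0);
}
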