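#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Marginal negative log-likelihood of a Poisson GLMM with one Gaussian
// random intercept per group (animal), integrated by adaptive
// Gauss-Hermite quadrature.  Rows must be ordered by group; gstart/gend
// are 0-based inclusive row ranges per group.  ghz/ghw are standard
// (physicists') Gauss-Hermite nodes and weights for \int e^{-z^2} f(z) dz.
// With sigma == 0 the likelihood degenerates to the plain Poisson GLM.

static double groupLogLik(const NumericVector &eta0, const NumericVector &y,
                          int lo, int hi, double sigma,
                          const NumericVector &ghz, const NumericVector &ghw,
                          double *mode_out) {
  double ll = 0.0;
  if (sigma < 1e-10) {
    for (int i = lo; i <= hi; ++i)
      ll += y[i] * eta0[i] - std::exp(eta0[i]) - std::lgamma(y[i] + 1.0);
    if (mode_out) *mode_out = 0.0;
    return ll;
  }
  const double s2 = sigma * sigma;
  double sy = 0.0;
  for (int i = lo; i <= hi; ++i) sy += y[i];
  // Newton for the mode of h(u) = sum(y*(eta0+u) - exp(eta0+u)) - u^2/(2 s2)
  double u = 0.0;
  for (int it = 0; it < 100; ++it) {
    double se = 0.0;
    for (int i = lo; i <= hi; ++i) se += std::exp(eta0[i] + u);
    const double g1 = sy - se - u / s2;
    const double g2 = -se - 1.0 / s2;
    double step = g1 / g2;
    if (step > 2.0) step = 2.0;
    if (step < -2.0) step = -2.0;
    u -= step;
    if (std::fabs(step) < 1e-12) break;
  }
  if (mode_out) *mode_out = u;
  double se = 0.0;
  for (int i = lo; i <= hi; ++i) se += std::exp(eta0[i] + u);
  const double h2 = -se - 1.0 / s2; // h''(u) at mode, < 0
  const double tau = 1.0 / std::sqrt(-h2);
  const double sqrt2tau = std::sqrt(2.0) * tau;
  // h at mode (for stable exponentials)
  double hmode = -0.5 * u * u / s2;
  for (int i = lo; i <= hi; ++i)
    hmode += y[i] * (eta0[i] + u) - std::exp(eta0[i] + u) -
             std::lgamma(y[i] + 1.0);
  double acc = 0.0;
  const int K = ghz.size();
  for (int k = 0; k < K; ++k) {
    const double uk = u + sqrt2tau * ghz[k];
    double h = -0.5 * uk * uk / s2;
    for (int i = lo; i <= hi; ++i)
      h += y[i] * (eta0[i] + uk) - std::exp(eta0[i] + uk) -
           std::lgamma(y[i] + 1.0);
    acc += ghw[k] * std::exp(h - hmode + ghz[k] * ghz[k]);
  }
  // marginal: int exp(h(u)) du / (sigma sqrt(2 pi))
  ll = hmode + std::log(acc) + std::log(sqrt2tau) -
       std::log(sigma * std::sqrt(2.0 * M_PI));
  return ll;
}

// [[Rcpp::export]]
double cppGlmmNll(NumericVector beta, double sigma, NumericMatrix X,
                  NumericVector off, NumericVector y, IntegerVector gstart,
                  IntegerVector gend, NumericVector ghz, NumericVector ghw) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector eta0(n);
  for (int i = 0; i < n; ++i) {
    double e = off[i];
    for (int j = 0; j < p; ++j) e += X(i, j) * beta[j];
    eta0[i] = e;
  }
  double ll = 0.0;
  for (int g = 0; g < gstart.size(); ++g)
    ll += groupLogLik(eta0, y, gstart[g], gend[g], sigma, ghz, ghw, nullptr);
  if (!std::isfinite(ll)) return 1e10;
  return -ll;
}

// posterior modes (empirical Bayes estimates) of the per-group intercepts
// [[Rcpp::export]]
NumericVector cppGlmmModes(NumericVector beta, double sigma, NumericMatrix X,
                           NumericVector off, NumericVector y,
                           IntegerVector gstart, IntegerVector gend,
                           NumericVector ghz, NumericVector ghw) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector eta0(n);
  for (int i = 0; i < n; ++i) {
    double e = off[i];
    for (int j = 0; j < p; ++j) e += X(i, j) * beta[j];
    eta0[i] = e;
  }
  NumericVector modes(gstart.size());
  for (int g = 0; g < gstart.size(); ++g) {
    double m = 0.0;
    groupLogLik(eta0, y, gstart[g], gend[g], sigma, ghz, ghw, &m);
    modes[g] = m;
  }
  return modes;
}
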