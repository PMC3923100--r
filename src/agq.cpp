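#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// log expit / log(1 - expit), stable for large |eta|
static inline double log_expit(double eta) {
  return eta >= 0.0 ? -std::log1p(std::exp(-eta)) : eta - std::log1p(std::exp(eta));
}

// Negative marginal log-likelihood of a random-intercept logistic model,
// the intercept integrated out per cluster by adaptive Gauss-Hermite
// quadrature centred at the conditional mode.
//
// par    : (beta_1..beta_p, sigma), sigma >= 0
// X      : n x p design matrix, rows sorted by cluster
// y      : 0/1 outcomes
// starts : length J+1, 0-based row offsets of each cluster (starts[J] = n)
// nodes, wts : Gauss-Hermite nodes and weights for weight exp(-z^2)
// [[Rcpp::export]]
double agq_nll(NumericVector par, NumericMatrix X, NumericVector y,
               IntegerVector starts, NumericVector nodes, NumericVector wts) {
  const int p = X.ncol();
  const int n = X.nrow();
  const int J = starts.size() - 1;
  const int K = nodes.size();
  const double sigma = par[p];

  std::vector<double> eta0(n);
  for (int i = 0; i < n; ++i) {
    double e = 0.0;
    for (int k = 0; k < p; ++k) e += X(i, k) * par[k];
    eta0[i] = e;
  }

  if (sigma < 1e-10) {  // degenerate: plain logistic likelihood
    double nll = 0.0;
    for (int i = 0; i < n; ++i)
      nll -= (y[i] > 0.5) ? log_expit(eta0[i]) : log_expit(-eta0[i]);
    return nll;
  }

  const double s2 = sigma * sigma;
  const double lconst = -std::log(sigma) - 0.5 * std::log(2.0 * M_PI);
  double nll = 0.0;

  for (int j = 0; j < J; ++j) {
    const int a = starts[j], b = starts[j + 1];
    // Newton iteration for the mode of h(u) = loglik_j(u) - u^2 / (2 s2);
    // h'' <= -1/s2 < 0, so the mode is unique and finite.
    double u = 0.0, hpp = -1.0 / s2;
    for (int it = 0; it < 60; ++it) {
      double g = -u / s2;
      hpp = -1.0 / s2;
      for (int i = a; i < b; ++i) {
        double pr = 1.0 / (1.0 + std::exp(-(eta0[i] + u)));
        g += y[i] - pr;
        hpp -= pr * (1.0 - pr);
      }
      double step = g / hpp;
      u -= step;
      if (std::fabs(step) < 1e-11) break;
    }
    // curvature and value at the mode
    double hm = -u * u / (2.0 * s2);
    hpp = -1.0 / s2;
    for (int i = a; i < b; ++i) {
      double et = eta0[i] + u;
      double pr = 1.0 / (1.0 + std::exp(-et));
      hpp -= pr * (1.0 - pr);
      hm += (y[i] > 0.5) ? log_expit(et) : log_expit(-et);
    }
    const double sj = 1.0 / std::sqrt(-hpp);
    double acc = 0.0;
    for (int k = 0; k < K; ++k) {
      const double uk = u + M_SQRT2 * sj * nodes[k];
      double hk = -uk * uk / (2.0 * s2);
      for (int i = a; i < b; ++i) {
        double et = eta0[i] + uk;
        hk += (y[i] > 0.5) ? log_expit(et) : log_expit(-et);
      }
      acc += wts[k] * std::exp(nodes[k] * nodes[k] + hk - hm);
    }
    nll -= lconst + 0.5 * std::log(2.0) + std::log(sj) + hm + std::log(acc);
  }
  return nll;
}
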