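// Inner loop of the profile-likelihood grid search: one reduced GLM fit per
// candidate threshold. This loop runs ~10^5-10^6 times in the Monte Carlo
// studies, so it is implemented in C++; the R-level fit_glm() is the
// reference implementation and the two are compared in the test suite.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// overflow-safe log(1 + exp(eta))
static inline double log1p_exp(double e) {
  return (e > 0.0 ? e : 0.0) + std::log1p(std::exp(-std::fabs(e)));
}

// y: response; Z: threshold-independent design block; XX: n x (p*M)
// stacked threshold-dependent columns, candidate-major; p: columns per
// candidate; logistic: 1 for the logistic link, 0 for the linear link.
// Returns the maximized reduced-model log-likelihood per candidate
// (NaN where the fit failed), matching profile_core() in R.
// [[Rcpp::export]]
arma::vec profile_core_cpp(const arma::vec& y, const arma::mat& Z,
                           const arma::mat& XX, const int p,
                           const int logistic) {
  const uword n = y.n_elem;
  const uword k0 = Z.n_cols;
  const uword M = XX.n_cols / p;
  const uword kk = k0 + p;
  vec out(M);
  out.fill(datum::nan);
  mat des(n, kk);
  des.cols(0, k0 - 1) = Z;

  if (!logistic) {
    for (uword m = 0; m < M; ++m) {
      des.cols(k0, kk - 1) = XX.cols(m * p, m * p + p - 1);
      mat ch;
      if (!chol(ch, des.t() * des)) continue;
      vec cf = solve(trimatu(ch),
                     vec(solve(trimatl(ch.t()), vec(des.t() * y))));
      double rss = accu(square(y - des * cf));
      // an interpolating fit has unbounded Gaussian likelihood
      out[m] = rss > 0.0
        ? -0.5 * n * (std::log(2.0 * datum::pi * rss / n) + 1.0)
        : datum::inf;
    }
    return out;
  }

  const vec beta0(kk, fill::zeros);
  vec beta = beta0;
  vec te(n), mu(n), w(n);
  for (uword m = 0; m < M; ++m) {
    des.cols(k0, kk - 1) = XX.cols(m * p, m * p + p - 1);
    vec b = beta;  // warm start from the previous candidate
    vec eta = des * b;
    // one exp pass per iteration: te = exp(-|eta|) serves both the
    // Bernoulli log-likelihood and the next iteration's mean/weights
    for (uword i = 0; i < n; ++i) te[i] = std::exp(-std::fabs(eta[i]));
    double dev_old = datum::inf;
    bool ok = false;
    for (int it = 0; it < 100; ++it) {
      for (uword i = 0; i < n; ++i) {
        mu[i] = eta[i] >= 0.0 ? 1.0 / (1.0 + te[i]) : te[i] / (1.0 + te[i]);
        double wi = mu[i] * (1.0 - mu[i]);
        w[i] = wi < 1e-10 ? 1e-10 : wi;
      }
      mat ch;
      if (!chol(ch, des.t() * (des.each_col() % w))) break;
      vec rhs = des.t() * (w % eta + (y - mu));
      vec b_prev = b;
      b = solve(trimatu(ch), vec(solve(trimatl(ch.t()), rhs)));
      eta = des * b;
      double ll = 0.0;
      for (uword i = 0; i < n; ++i) {
        te[i] = std::exp(-std::fabs(eta[i]));
        ll += y[i] * eta[i] -
          ((eta[i] > 0.0 ? eta[i] : 0.0) + std::log1p(te[i]));
      }
      double dev = -2.0 * ll;
      // step-halving keeps the ascent property when a full Newton step
      // overshoots (IRLS is not globally convergent from poor starts)
      for (int h = 0; h < 30 && !(dev <= dev_old); ++h) {
        b = 0.5 * (b + b_prev);
        eta = des * b;
        ll = 0.0;
        for (uword i = 0; i < n; ++i) {
          te[i] = std::exp(-std::fabs(eta[i]));
          ll += y[i] * eta[i] -
            ((eta[i] > 0.0 ? eta[i] : 0.0) + std::log1p(te[i]));
        }
        dev = -2.0 * ll;
      }
      double relchg = (abs(b - b_prev) / (abs(b_prev) + 1e-4)).max();
      bool dev_settled = std::isfinite(dev) &&
        std::fabs(dev - dev_old) / (std::fabs(dev) + 0.1) < 1e-8;
      // deviance alone can plateau on a separated ridge while the
      // coefficients still drift; require both to settle
      if (dev_settled && relchg < 1e-4) {
        ok = true;
        dev_old = dev;
        break;
      }
      // settled deviance with a runaway linear predictor is a separated
      // ridge; no point iterating to the cap
      if (dev_settled && abs(eta).max() > 30.0) break;
      dev_old = dev;
    }
    // a settled fit with an extreme linear predictor is quasi-separated:
    // the likelihood has no usable interior maximum there
    if (ok && abs(eta).max() > 30.0) ok = false;
    if (ok) {
      out[m] = -0.5 * dev_old;
      beta = b;
    } else {
      beta = beta0;
    }
  }
  return out;
}
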