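// Core likelihood kernels for the zero-inflated generalized Poisson (ZIGP)
// factor model.  Everything is evaluated in log space; the mean-parameterized
// GP pmf is
//   p(y; mu, alpha) = (1/y!) (mu/(1+a*mu))^y (1+a*y)^(y-1)
//                     * exp{-mu(1+a*y)/(1+a*mu)},  alpha >= 0,
// and the structural-zero probability is tied to the rate by
//   logit(phi) = -tau * log(lambda),  i.e. phi = sigmoid(-tau * eta)
// with eta = log(lambda).  The GP mean is mu = T * lambda, so
// log(mu) = eta + log(T).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double LE_CAP = 300.0;   // cap on log(mu); keeps exp() finite

static inline double softplus(double x) {
  if (x > 33.0) return x;
  if (x < -33.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// log(1 + alpha * mu) given le = log(mu), overflow-safe
static inline double log1p_alpha_mu(double alpha, double le) {
  if (alpha <= 0.0) return 0.0;
  double t = std::log(alpha) + le;
  if (t > 33.0) return t;
  return std::log1p(std::exp(t));
}

// GP log pmf given y, le = log(mu), alpha; lr = le - log(1+alpha*mu)
static inline double gp_logpmf_le(double y, double le, double alpha) {
  double l1am = log1p_alpha_mu(alpha, le);
  double lr = le - l1am;
  double out = -(1.0 + alpha * y) * std::exp(lr);
  if (y > 0.0) {
    out += y * lr + (y - 1.0) * std::log1p(alpha * y) - std::lgamma(y + 1.0);
  }
  return out;
}

// [[Rcpp::export(name = ".gz_gp_logpmf")]]
NumericVector gz_gp_logpmf(NumericVector y, NumericVector mu, double alpha) {
  R_xlen_t n = y.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double m = mu[(mu.size() == n) ? i : 0];
    out[i] = gp_logpmf_le(y[i], std::log(m), alpha);
  }
  return out;
}

// Observed-data ZIGP log-likelihood over weighted entries.
// Y, Eta, W are n x m; logT length n; W is a 0/1 inclusion weight matrix.
// [[Rcpp::export(name = ".gz_obs_loglik")]]
double gz_obs_loglik(const arma::mat& Y, const arma::mat& Eta,
                     const arma::vec& logT, double tau, double alpha,
                     const arma::mat& W) {
  const arma::uword n = Y.n_rows, m = Y.n_cols;
  double ll = 0.0;
  for (arma::uword j = 0; j < m; ++j) {
    for (arma::uword i = 0; i < n; ++i) {
      double w = W(i, j);
      if (w == 0.0) continue;
      double eta = Eta(i, j);
      double le = eta + logT(i);
      if (le > LE_CAP) le = LE_CAP;
      double s = tau * eta;
      double lphi = -softplus(s);
      double l1mphi = -softplus(-s);
      double y = Y(i, j);
      if (y > 0.0) {
        ll += w * (l1mphi + gp_logpmf_le(y, le, alpha));
      } else {
        double lp0 = gp_logpmf_le(0.0, le, alpha);
        double a = lphi, b = l1mphi + lp0;
        double mx = (a > b) ? a : b;
        ll += w * (mx + std::log(std::exp(a - mx) + std::exp(b - mx)));
      }
    }
  }
  return ll;
}

// E-step: posterior probability that each observed zero is a structural zero.
// [[Rcpp::export(name = ".gz_estep")]]
arma::mat gz_estep(const arma::mat& Y, const arma::mat& Eta,
                   const arma::vec& logT, double tau, double alpha) {
  const arma::uword n = Y.n_rows, m = Y.n_cols;
  arma::mat Z(n, m, arma::fill::zeros);
  for (arma::uword j = 0; j < m; ++j) {
    for (arma::uword i = 0; i < n; ++i) {
      if (Y(i, j) > 0.0) continue;
      double eta = Eta(i, j);
      double le = eta + logT(i);
      if (le > LE_CAP) le = LE_CAP;
      double s = tau * eta;
      double lphi = -softplus(s);
      double l1mphi = -softplus(-s);
      double lp0 = gp_logpmf_le(0.0, le, alpha);
      double a = lphi, b = l1mphi + lp0;
      double mx = (a > b) ? a : b;
      double lmix = mx + std::log(std::exp(a - mx) + std::exp(b - mx));
      Z(i, j) = std::exp(lphi - lmix);
    }
  }
  return Z;
}

// Expected complete-data log-likelihood Q and its gradients.
// Q = sum w * [ z*log(phi) + (1-z)*log(1-phi) + (1-z)*gp_logpmf(y) ]
// Returns Q, dQ/dEta (n x m), dQ/dtau, dQ/dalpha.
// [[Rcpp::export(name = ".gz_q_grad")]]
List gz_q_grad(const arma::mat& Y, const arma::mat& Z, const arma::mat& Eta,
               const arma::vec& logT, double tau, double alpha,
               const arma::mat& W) {
  const arma::uword n = Y.n_rows, m = Y.n_cols;
  arma::mat G(n, m, arma::fill::zeros);
  double Q = 0.0, gtau = 0.0, galpha = 0.0;
  for (arma::uword j = 0; j < m; ++j) {
    for (arma::uword i = 0; i < n; ++i) {
      double w = W(i, j);
      if (w == 0.0) continue;
      double eta = Eta(i, j);
      double le = eta + logT(i);
      if (le > LE_CAP) le = LE_CAP;
      double y = Y(i, j);
      double z = Z(i, j);
      double s = tau * eta;
      double lphi = -softplus(s);
      double l1mphi = -softplus(-s);
      double phi = std::exp(lphi);
      double l1am = log1p_alpha_mu(alpha, le);
      double lr = le - l1am;           // log(mu/(1+a*mu))
      double elr = std::exp(lr);
      double lgp = -(1.0 + alpha * y) * elr;
      if (y > 0.0) {
        lgp += y * lr + (y - 1.0) * std::log1p(alpha * y) -
               std::lgamma(y + 1.0);
      }
      Q += w * (z * lphi + (1.0 - z) * (l1mphi + lgp));
      // d/deta
      double dgp_deta =
          y * std::exp(-l1am) - (1.0 + alpha * y) * std::exp(lr - l1am);
      G(i, j) = w * (tau * (phi - z) + (1.0 - z) * dgp_deta);
      gtau += w * eta * (phi - z);
      // d(gp logpmf)/dalpha
      double resid = y * std::exp(-l1am) - elr;  // (y - mu)/(1 + a*mu)
      double dgp_da = -y * elr - elr * resid;
      if (y > 0.0) dgp_da += y * (y - 1.0) / (1.0 + alpha * y);
      galpha += w * (1.0 - z) * dgp_da;
    }
  }
  return List::create(_["Q"] = Q, _["Geta"] = G, _["gtau"] = gtau,
                      _["galpha"] = galpha);
}

// Observed-data log-likelihood with analytic gradient in (tau, alpha).
// [[Rcpp::export(name = ".gz_obs_ta_grad")]]
NumericVector gz_obs_ta_grad(const arma::mat& Y, const arma::mat& Eta,
                             const arma::vec& logT, double tau, double alpha,
                             const arma::mat& W) {
  const arma::uword n = Y.n_rows, m = Y.n_cols;
  double ll = 0.0, gtau = 0.0, galpha = 0.0;
  for (arma::uword j = 0; j < m; ++j) {
    for (arma::uword i = 0; i < n; ++i) {
      double w = W(i, j);
      if (w == 0.0) continue;
      double eta = Eta(i, j);
      double le = eta + logT(i);
      if (le > LE_CAP) le = LE_CAP;
      double y = Y(i, j);
      double s = tau * eta;
      double lphi = -softplus(s);
      double l1mphi = -softplus(-s);
      double phi = std::exp(lphi);
      double l1am = log1p_alpha_mu(alpha, le);
      double lr = le - l1am;
      double elr = std::exp(lr);
      if (y > 0.0) {
        double lgp = y * lr + (y - 1.0) * std::log1p(alpha * y) -
                     (1.0 + alpha * y) * elr - std::lgamma(y + 1.0);
        ll += w * (l1mphi + lgp);
        gtau += w * eta * phi;
        double resid = y * std::exp(-l1am) - elr;
        double dgp_da =
            -y * elr + y * (y - 1.0) / (1.0 + alpha * y) - elr * resid;
        galpha += w * dgp_da;
      } else {
        double lp0 = -elr;
        double a = lphi, b = l1mphi + lp0;
        double mx = (a > b) ? a : b;
        double lmix = mx + std::log(std::exp(a - mx) + std::exp(b - mx));
        ll += w * lmix;
        // gradients of lmix in log space to avoid 0 * Inf at extreme rates
        double l1mp0 = (lp0 > -0.693147180559945)
                           ? std::log(-std::expm1(lp0))
                           : std::log1p(-std::exp(lp0));
        // d lmix/dtau = -eta * phi * (1-phi) * (1 - p0) / mix
        gtau += w * (-eta) * std::exp(lphi + l1mphi + l1mp0 - lmix);
        // d lmix/dalpha = (1-phi) * p0 * mu^2/(1+a*mu)^2 / mix
        galpha += w * std::exp(l1mphi + lp0 + 2.0 * lr - lmix);
      }
    }
  }
  return NumericVector::create(ll, gtau, galpha);
}

// Exact inversion sampling of the GP distribution via cumulative-pmf scan.
// Uses R's RNG so draws are governed by set.seed().
// [[Rcpp::export(name = ".gz_gp_sample")]]
IntegerVector gz_gp_sample(NumericVector mu, double alpha) {
  R_xlen_t n = mu.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double u = unif_rand();
    double le = std::log(mu[i]);
    double y = 0.0;
    double cum = std::exp(gp_logpmf_le(0.0, le, alpha));
    while (cum < u && y < 1e7) {
      y += 1.0;
      double p = std::exp(gp_logpmf_le(y, le, alpha));
      cum += p;
      // guard against a cumulative sum that saturates just below u
      if (p < 1e-18 && y > mu[i]) break;
    }
    out[i] = static_cast<int>(y);
  }
  return out;
}
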