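#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double LN2 = 0.6931471805599453;

// NB log-likelihood terms that depend on mu (lgamma constants dropped:
// they cancel when the grid posterior is normalized).
// r = 1/alpha; Poisson limit used when alpha < 1e-12.
static inline double ll_term(double k, double mu, double alpha) {
  if (alpha < 1e-12) return k * std::log(mu) - mu;
  double r = 1.0 / alpha;
  return r * std::log(r / (r + mu)) + k * std::log(mu / (r + mu));
}

// Profile out the intercept phi for a single value of beta.
// mu_i = c_i * phi with c_i = s_i * 2^(x_i * beta); Newton iteration on
// u = log(phi). Score and curvature have closed forms free of lgamma.
static double profile_once(const NumericVector& k, const NumericVector& c,
                           const NumericVector& alpha, double tol, int max_iter,
                           double* warm) {
  int m = k.size();
  double ksum = 0.0, csum = 0.0;
  for (int i = 0; i < m; ++i) { ksum += k[i]; csum += c[i]; }
  if (ksum <= 0.0) return 0.0;  // likelihood flat-topped at phi -> 0
  // warm start from the previous grid point's solution when available
  // (consecutive betas move phi-hat only slightly)
  double u = (warm != NULL && R_finite(*warm)) ? *warm
                                               : std::log(ksum / csum);
  for (int it = 0; it < max_iter; ++it) {
    double phi = std::exp(u);
    double score = 0.0, hess = 0.0;
    for (int i = 0; i < m; ++i) {
      double mu = c[i] * phi;
      if (alpha[i] < 1e-12) {
        score += k[i] - mu;
        hess -= mu;
      } else {
        double r = 1.0 / alpha[i];
        double denom = r + mu;
        score += k[i] - mu * (k[i] + r) / denom;
        hess -= (k[i] + r) * r * mu / (denom * denom);
      }
    }
    double step = -score / hess;
    if (step > 2.0) step = 2.0; else if (step < -2.0) step = -2.0;
    u += step;
    if (std::fabs(step) < tol) break;
  }
  if (warm != NULL) *warm = u;
  double phi = std::exp(u), ll = 0.0;
  for (int i = 0; i < m; ++i) ll += ll_term(k[i], c[i] * phi, alpha[i]);
  return ll;
}

// [[Rcpp::export(name = ".profile_loglik_grid")]]
NumericVector profile_loglik_grid(NumericVector k, NumericVector s,
                                  NumericVector x, NumericVector alpha,
                                  NumericVector betas,
                                  double tol = 1e-8, int max_iter = 100) {
  int n = betas.size(), m = k.size();
  NumericVector out(n);
  NumericVector c(m);
  double warm = NA_REAL;
  for (int b = 0; b < n; ++b) {
    double beta = betas[b];
    for (int i = 0; i < m; ++i) c[i] = s[i] * std::exp(LN2 * x[i] * beta);
    out[b] = profile_once(k, c, alpha, tol, max_iter, &warm);
  }
  return out;
}

// Plug-in variant: phi held fixed rather than profiled.
// [[Rcpp::export(name = ".plugin_loglik_grid")]]
NumericVector plugin_loglik_grid(NumericVector k, NumericVector s,
                                 NumericVector x, NumericVector alpha,
                                 NumericVector betas, double phi) {
  int n = betas.size(), m = k.size();
  NumericVector out(n);
  for (int b = 0; b < n; ++b) {
    double beta = betas[b], ll = 0.0;
    for (int i = 0; i < m; ++i) {
      double mu = s[i] * std::exp(LN2 * x[i] * beta) * phi;
      ll += ll_term(k[i], mu, alpha[i]);
    }
    out[b] = ll;
  }
  return out;
}
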