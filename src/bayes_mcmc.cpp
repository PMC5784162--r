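// Gibbs samplers for whole-genome Bayesian marker regressions.
// Models: 0 = BayesA (scaled-t), 1 = BayesB (point mass + scaled-t,
// fixed mixing proportion), 2 = BayesC-pi (point mass + Gaussian, pi
// sampled), 3 = Bayesian LASSO (double-exponential, Park & Casella).
// Residual-update scheme: e always holds y - mu - W beta.

#include <Rcpp.h>
using namespace Rcpp;

// Michael-Schucany-Haas inverse-Gaussian sampler
static double rinvgauss(double mu, double lambda) {
  double v = R::norm_rand();
  double z = v * v;
  double x = mu + mu * mu * z / (2.0 * lambda) -
    mu / (2.0 * lambda) * std::sqrt(4.0 * mu * lambda * z + mu * mu * z * z);
  if (x <= 0) x = 1e-10;
  if (R::unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// [[Rcpp::export]]
List bayes_mcmc_cpp(NumericMatrix W, NumericVector y, int model,
                    int iters, int burnin, double pi_zero) {
  const int n = W.nrow(), m = W.ncol();
  const double vy = var(y);

  std::vector<double> x2(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    const double *wj = &W(0, j);
    for (int i = 0; i < n; ++i) s += wj[i] * wj[i];
    x2[j] = s;
  }
  double msx = 0.0;
  for (int j = 0; j < m; ++j) msx += x2[j];
  msx /= n;
  if (msx <= 0) stop("all markers are constant");

  const double R2 = 0.5;
  const double nu_e = 5.0, nu_b = 5.0;
  const double Se = (1.0 - R2) * vy * (nu_e + 2.0) / nu_e;
  double Sb;
  if (model == 1) Sb = R2 * vy / ((1.0 - pi_zero) * msx) * (nu_b + 2.0) / nu_b;
  else            Sb = R2 * vy / msx * (nu_b + 2.0) / nu_b;

  std::vector<double> beta(m, 0.0), s2b(m, Sb), tau2(m, 1.0);
  double sigma2e = vy * (1.0 - R2);
  double sigma2b = Sb;              // common variance (BayesC-pi)
  double pi = pi_zero;              // prob of exclusion
  double lambda2 = 2.0 * (1.0 - R2) / R2 * msx;  // BL regularization
  double mu = mean(y);

  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;

  std::vector<double> beta_sum(m, 0.0);
  double mu_sum = 0.0, s2e_sum = 0.0, pi_sum = 0.0;
  int nkeep = 0, bad_iter = -1;

  for (int it = 0; it < iters; ++it) {
    // intercept
    double ebar = 0.0;
    for (int i = 0; i < n; ++i) ebar += e[i];
    ebar /= n;
    double mu_new = mu + ebar + R::norm_rand() * std::sqrt(sigma2e / n);
    double dmu = mu_new - mu;
    for (int i = 0; i < n; ++i) e[i] -= dmu;
    mu = mu_new;

    int m_in = 0;
    double ssb_in = 0.0, sum_tau2 = 0.0;

    for (int j = 0; j < m; ++j) {
      if (x2[j] <= 0) { beta[j] = 0.0; continue; }
      const double *wj = &W(0, j);
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += wj[i] * e[i];
      rhs += x2[j] * beta[j];

      double beta_new = 0.0;
      bool in_model = true;

      if (model == 1 || model == 2) {
        double vb = (model == 1) ? s2b[j] : sigma2b;
        double v1 = x2[j] * x2[j] * vb + x2[j] * sigma2e;
        double v0 = x2[j] * sigma2e;
        double log1 = std::log(1.0 - pi) - 0.5 * std::log(v1) -
          0.5 * rhs * rhs / v1;
        double log0 = std::log(pi) - 0.5 * std::log(v0) -
          0.5 * rhs * rhs / v0;
        double p1 = 1.0 / (1.0 + std::exp(log0 - log1));
        in_model = (R::unif_rand() < p1);
      }

      if (in_model) {
        double prior_prec;
        if (model == 3) {
          prior_prec = 1.0 / tau2[j];   // beta ~ N(0, tau2 * sigma2e)
          double C = x2[j] + prior_prec;
          beta_new = rhs / C + R::norm_rand() * std::sqrt(sigma2e / C);
        } else {
          double vb = (model == 2) ? sigma2b : s2b[j];
          double C = x2[j] + sigma2e / vb;
          beta_new = rhs / C + R::norm_rand() * std::sqrt(sigma2e / C);
        }
        ++m_in;
        ssb_in += beta_new * beta_new;
      }

      double db = beta_new - beta[j];
      if (db != 0.0) for (int i = 0; i < n; ++i) e[i] -= wj[i] * db;
      beta[j] = beta_new;

      // marker-variance updates
      if (model == 0) {
        s2b[j] = (Sb * nu_b + beta[j] * beta[j]) /
          R::rchisq(nu_b + 1.0);
      } else if (model == 1) {
        if (in_model)
          s2b[j] = (Sb * nu_b + beta[j] * beta[j]) / R::rchisq(nu_b + 1.0);
        else
          s2b[j] = Sb * nu_b / R::rchisq(nu_b);
      } else if (model == 3) {
        double b2 = beta[j] * beta[j];
        if (b2 < 1e-12) b2 = 1e-12;
        double mu_ig = std::sqrt(lambda2 * sigma2e / b2);
        if (mu_ig > 1e8) mu_ig = 1e8;
        double inv_tau2 = rinvgauss(mu_ig, lambda2);
        tau2[j] = 1.0 / inv_tau2;
        sum_tau2 += tau2[j];
      }
    }

    if (model == 2) {
      sigma2b = (Sb * nu_b + ssb_in) / R::rchisq(nu_b + m_in);
      pi = R::rbeta(m - m_in + 1.0, m_in + 1.0);
      if (pi > 0.999) pi = 0.999;
      if (pi < 0.001) pi = 0.001;
    }
    if (model == 3) {
      // lambda^2 ~ Gamma(shape, rate); diffuse hyperprior
      lambda2 = R::rgamma(m + 1.2, 1.0 / (sum_tau2 / 2.0 + 1e-4));
      if (lambda2 < 1e-8) lambda2 = 1e-8;
    }

    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    sigma2e = (sse + Se * nu_e) / R::rchisq(n + nu_e);

    if (!R_finite(sigma2e) || !R_finite(mu)) { bad_iter = it + 1; break; }

    if (it >= burnin) {
      for (int j = 0; j < m; ++j) beta_sum[j] += beta[j];
      mu_sum += mu;
      s2e_sum += sigma2e;
      pi_sum += pi;
      ++nkeep;
    }
  }

  NumericVector eff(m);
  if (nkeep > 0)
    for (int j = 0; j < m; ++j) eff[j] = beta_sum[j] / nkeep;
  if (bad_iter > 0) for (int j = 0; j < m; ++j) eff[j] = NA_REAL;

  return List::create(_["effects"] = eff,
                      _["mu"] = nkeep > 0 ? mu_sum / nkeep : NA_REAL,
                      _["sigma2e"] = nkeep > 0 ? s2e_sum / nkeep : NA_REAL,
                      _["pi_zero"] = nkeep > 0 ? pi_sum / nkeep : NA_REAL,
                      _["bad_iter"] = bad_iter);
}
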