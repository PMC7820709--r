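// Compiled Gibbs sweeps for the quantile and mean-regression multilevel
// IRT samplers.  All randomness goes through R's RNG (RNGScope), so runs
// are reproducible under set.seed() from the R side.  The pure-R step
// functions in R/steps.R are the reference implementations; this engine
// exists because a 10,000-iteration chain over n x K truncated-normal
// augmentations is the hot loop of every study.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// ---- primitive draws ------------------------------------------------------

// Standard normal truncated to (lo, Inf).  Plain rejection near the bulk,
// Robert's translated-exponential rejection in the tail.
static double rtnorm_std_lower(double lo) {
  if (lo < 0.45) {
    for (;;) {
      double s = R::norm_rand();
      if (s > lo) return s;
    }
  }
  const double lambda = 0.5 * (lo + std::sqrt(lo * lo + 4.0));
  for (;;) {
    double s = lo + R::exp_rand() / lambda;
    double d = s - lambda;
    if (R::unif_rand() <= std::exp(-0.5 * d * d)) return s;
  }
}

// N(mu, sd^2) truncated below at 0.
static double rtnorm_lower0(double mu, double sd) {
  return mu + sd * rtnorm_std_lower(-mu / sd);
}

// Inverse-Gaussian(mean, shape); small root through the product of roots
// for numerical stability.
static double rinvgauss1(double mu, double lambda) {
  double y = R::norm_rand();
  y *= y;
  double xplus = mu + mu * mu * y / (2.0 * lambda) +
    mu / (2.0 * lambda) * std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  double xminus = mu * mu / xplus;
  return (R::unif_rand() <= mu / (mu + xminus)) ? xminus : xplus;
}

// ---- shared measurement-level sweep steps ---------------------------------

// Step 1: augmented data z (only observed cells touched).
static void step_z(const IntegerMatrix& Y, const arma::vec& theta,
                   const arma::vec& a, const arma::vec& b, arma::mat& z) {
  const int n = Y.nrow(), K = Y.ncol();
  for (int k = 0; k < K; ++k) {
    const double ak = a[k], bk = b[k];
    for (int i = 0; i < n; ++i) {
      const int y = Y(i, k);
      if (y == NA_INTEGER) continue;
      const double eta = ak * (theta[i] - bk);
      z(i, k) = y == 1 ? eta + rtnorm_std_lower(-eta)
                       : eta - rtnorm_std_lower(eta);
    }
  }
}

// Steps 2-3: item parameters (anchor skipped).
static void step_items(const IntegerMatrix& Y, const arma::mat& z,
                       const arma::vec& theta, arma::vec& a, arma::vec& b,
                       int anchor, double mu_a, double sa2, double mu_b,
                       double sb2) {
  const int n = Y.nrow(), K = Y.ncol();
  for (int k = 0; k < K; ++k) {
    if (k == anchor) continue;
    double Sxx = 0.0, Sxz = 0.0;
    for (int i = 0; i < n; ++i) {
      if (Y(i, k) == NA_INTEGER) continue;
      const double d = theta[i] - b[k];
      Sxx += d * d;
      Sxz += z(i, k) * d;
    }
    double v = 1.0 / (1.0 / sa2 + Sxx);
    double m = v * (mu_a / sa2 + Sxz);
    a[k] = rtnorm_lower0(m, std::sqrt(v));
  }
  for (int k = 0; k < K; ++k) {
    if (k == anchor) continue;
    double s = 0.0;
    int nk = 0;
    for (int i = 0; i < n; ++i) {
      if (Y(i, k) == NA_INTEGER) continue;
      s += z(i, k) - a[k] * theta[i];
      ++nk;
    }
    double v = 1.0 / (1.0 / sb2 + nk * a[k] * a[k]);
    double m = v * (mu_b / sb2 - a[k] * s);
    b[k] = m + std::sqrt(v) * R::norm_rand();
  }
}

// Step 4: abilities, given per-person structural prior (pm, pv).
static void step_theta(const IntegerMatrix& Y, const arma::mat& z,
                       const arma::vec& a, const arma::vec& b,
                       const arma::vec& pm, const arma::vec& pv,
                       arma::vec& theta) {
  const int n = Y.nrow(), K = Y.ncol();
  for (int i = 0; i < n; ++i) {
    double Sa2 = 0.0, Szb = 0.0;
    for (int k = 0; k < K; ++k) {
      if (Y(i, k) == NA_INTEGER) continue;
      Sa2 += a[k] * a[k];
      Szb += a[k] * (z(i, k) + a[k] * b[k]);
    }
    double v = 1.0 / (1.0 / pv[i] + Sa2);
    double m = v * (pm[i] / pv[i] + Szb);
    theta[i] = m + std::sqrt(v) * R::norm_rand();
  }
}

// Multivariate normal draw given precision matrix and linear term.
static arma::vec draw_mvn(const arma::mat& prec, const arma::vec& rhs) {
  arma::mat U = arma::chol(prec);                  // upper triangular
  arma::vec m = arma::solve(arma::trimatu(U),
                            arma::solve(arma::trimatl(U.t()), rhs));
  arma::vec zq(rhs.n_elem);
  for (arma::uword j = 0; j < zq.n_elem; ++j) zq[j] = R::norm_rand();
  return m + arma::solve(arma::trimatu(U), zq);
}

// -2 log f(Z | theta, xi): normal measurement density at observed cells.
static double meas_deviance(const IntegerMatrix& Y, const arma::mat& z,
                            const arma::vec& theta, const arma::vec& a,
                            const arma::vec& b) {
  const int n = Y.nrow(), K = Y.ncol();
  double ll = 0.0;
  for (int k = 0; k < K; ++k) {
    for (int i = 0; i < n; ++i) {
      if (Y(i, k) == NA_INTEGER) continue;
      const double r = z(i, k) - a[k] * (theta[i] - b[k]);
      ll += -0.5 * (std::log(2.0 * M_PI) + r * r);
    }
  }
  return -2.0 * ll;
}

// -2 log f(Y | theta, xi): observed-scale Bernoulli deviance (clipped).
static double obs_deviance(const IntegerMatrix& Y, const arma::vec& theta,
                           const arma::vec& a, const arma::vec& b) {
  const int n = Y.nrow(), K = Y.ncol();
  double ll = 0.0;
  for (int k = 0; k < K; ++k) {
    for (int i = 0; i < n; ++i) {
      const int y = Y(i, k);
      if (y == NA_INTEGER) continue;
      double p = R::pnorm(a[k] * (theta[i] - b[k]), 0.0, 1.0, 1, 0);
      if (p < 1e-12) p = 1e-12;
      if (p > 1.0 - 1e-12) p = 1.0 - 1e-12;
      ll += y == 1 ? std::log(p) : std::log1p(-p);
    }
  }
  return -2.0 * ll;
}

// ---- quantile-model chain -------------------------------------------------

// [[Rcpp::export]]
List qmlirt_chain_cpp(IntegerMatrix Y, arma::mat X, double tau,
                      List hyper, int anchor, int n_iter, int burn_in,
                      int thin, bool store_theta, List init) {
  RNGScope scope;
  const int n = Y.nrow(), K = Y.ncol(), q = X.n_cols;
  const double d = tau * (1.0 - tau);
  const double k1 = (1.0 - 2.0 * tau) / d, k2 = 2.0 / d;
  const double c2 = 2.0 * k2 + k1 * k1;

  const double mu_a = hyper["mu_a"], sa2 = std::pow(as<double>(hyper["sigma_a"]), 2);
  const double mu_b = hyper["mu_b"], sb2 = std::pow(as<double>(hyper["sigma_b"]), 2);
  const double a0w = hyper["omega_shape"], b0w = hyper["omega_rate"];
  const arma::vec beta0 = as<arma::vec>(hyper["beta_mean"]);
  const arma::mat H0inv = arma::inv_sympd(as<arma::mat>(hyper["beta_cov"]));
  const arma::vec H0b0 = H0inv * beta0;

  arma::vec theta = as<arma::vec>(init["theta"]);
  arma::vec a = as<arma::vec>(init["a"]);
  arma::vec b = as<arma::vec>(init["b"]);
  arma::vec beta = as<arma::vec>(init["beta"]);
  double omega = init["omega"];
  arma::vec e = as<arma::vec>(init["e"]);
  arma::mat z(n, K, arma::fill::zeros);

  const int n_keep = (n_iter - burn_in) / thin;
  arma::mat keep_beta(n_keep, q), keep_a(n_keep, K), keep_b(n_keep, K);
  arma::vec keep_omega(n_keep), keep_dev(n_keep), keep_dev_obs(n_keep);
  arma::mat keep_theta;
  if (store_theta) keep_theta.set_size(n_keep, n);
  arma::vec sum_theta(n, arma::fill::zeros), sumsq_theta(n, arma::fill::zeros);
  arma::vec sum_e(n, arma::fill::zeros);
  arma::mat sum_z(n, K, arma::fill::zeros);

  arma::vec pm(n), pv(n), resid(n);
  int kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    step_z(Y, theta, a, b, z);
    step_items(Y, z, theta, a, b, anchor - 1, mu_a, sa2, mu_b, sb2);
    arma::vec xb = X * beta;
    pm = xb + k1 * e;
    pv = k2 * omega * e;
    step_theta(Y, z, a, b, pm, pv, theta);
    // Step 5: omega, collapsed over e.
    resid = theta - xb;
    double sum_rho = 0.0;
    for (int i = 0; i < n; ++i) {
      sum_rho += resid[i] * (tau - (resid[i] < 0 ? 1.0 : 0.0));
    }
    omega = 1.0 / R::rgamma(n + a0w, 1.0 / (b0w + sum_rho));
    // Step 6: latent mixing variables.
    const double lam = c2 / (k2 * omega);
    for (int i = 0; i < n; ++i) {
      double r = std::fabs(resid[i]);
      if (r < 1e-8) r = 1e-8;
      e[i] = 1.0 / rinvgauss1(std::sqrt(c2) / r, lam);
    }
    // Step 7: beta.
    {
      arma::vec w = 1.0 / (k2 * omega * e);
      arma::mat prec = H0inv + X.t() * (X.each_col() % w);
      arma::vec rhs = H0b0 + X.t() * ((theta - k1 * e) % w);
      beta = draw_mvn(prec, rhs);
    }

    if (it >= burn_in && (it - burn_in) % thin == thin - 1) {
      keep_beta.row(kept) = beta.t();
      keep_a.row(kept) = a.t();
      keep_b.row(kept) = b.t();
      keep_omega[kept] = omega;
      if (store_theta) keep_theta.row(kept) = theta.t();
      sum_theta += theta;
      sumsq_theta += arma::square(theta);
      sum_e += e;
      sum_z += z;
      // Joint deviance: measurement plus structural conditional normal.
      arma::vec xb2 = X * beta;
      double ll = 0.0;
      for (int i = 0; i < n; ++i) {
        const double m = xb2[i] + k1 * e[i];
        const double s2 = k2 * omega * e[i];
        const double r = theta[i] - m;
        ll += -0.5 * (std::log(2.0 * M_PI * s2) + r * r / s2);
      }
      keep_dev[kept] = meas_deviance(Y, z, theta, a, b) - 2.0 * ll;
      keep_dev_obs[kept] = obs_deviance(Y, theta, a, b) - 2.0 * ll;
      ++kept;
    }
  }

  List out = List::create(
    _["beta"] = keep_beta, _["a"] = keep_a, _["b"] = keep_b,
    _["omega"] = keep_omega, _["deviance"] = keep_dev,
    _["deviance_obs"] = keep_dev_obs,
    _["theta_mean"] = sum_theta / kept,
    _["theta_sd"] = arma::sqrt(arma::clamp(
        sumsq_theta / kept - arma::square(sum_theta / kept), 0.0,
        arma::datum::inf)),
    _["e_mean"] = sum_e / kept, _["z_mean"] = sum_z / kept);
  if (store_theta) out["theta"] = keep_theta;
  return out;
}

// ---- mean-regression baseline chain ---------------------------------------

// [[Rcpp::export]]
List mmlirt_chain_cpp(IntegerMatrix Y, arma::mat X, List hyper, int anchor,
                      int n_iter, int burn_in, int thin, bool store_theta,
                      List init) {
  RNGScope scope;
  const int n = Y.nrow(), K = Y.ncol(), q = X.n_cols;

  const double mu_a = hyper["mu_a"], sa2 = std::pow(as<double>(hyper["sigma_a"]), 2);
  const double mu_b = hyper["mu_b"], sb2 = std::pow(as<double>(hyper["sigma_b"]), 2);
  const double a0 = hyper["alpha2_shape"], b0 = hyper["alpha2_rate"];
  const arma::vec beta0 = as<arma::vec>(hyper["beta_mean"]);
  const arma::mat H0inv = arma::inv_sympd(as<arma::mat>(hyper["beta_cov"]));
  const arma::vec H0b0 = H0inv * beta0;

  arma::vec theta = as<arma::vec>(init["theta"]);
  arma::vec a = as<arma::vec>(init["a"]);
  arma::vec b = as<arma::vec>(init["b"]);
  arma::vec beta = as<arma::vec>(init["beta"]);
  double alpha2 = init["alpha2"];
  arma::mat z(n, K, arma::fill::zeros);

  const int n_keep = (n_iter - burn_in) / thin;
  arma::mat keep_beta(n_keep, q), keep_a(n_keep, K), keep_b(n_keep, K);
  arma::vec keep_alpha2(n_keep), keep_dev(n_keep), keep_dev_obs(n_keep);
  arma::mat keep_theta;
  if (store_theta) keep_theta.set_size(n_keep, n);
  arma::vec sum_theta(n, arma::fill::zeros), sumsq_theta(n, arma::fill::zeros);
  arma::mat sum_z(n, K, arma::fill::zeros);

  arma::vec pv(n);
  int kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    step_z(Y, theta, a, b, z);
    step_items(Y, z, theta, a, b, anchor - 1, mu_a, sa2, mu_b, sb2);
    arma::vec xb = X * beta;
    pv.fill(alpha2);
    step_theta(Y, z, a, b, xb, pv, theta);
    // Structural variance.
    arma::vec resid = theta - xb;
    alpha2 = 1.0 / R::rgamma(a0 + 0.5 * n,
                             1.0 / (b0 + 0.5 * arma::dot(resid, resid)));
    // Coefficients.
    {
      arma::mat prec = H0inv + X.t() * X / alpha2;
      arma::vec rhs = H0b0 + X.t() * theta / alpha2;
      beta = draw_mvn(prec, rhs);
    }

    if (it >= burn_in && (it - burn_in) % thin == thin - 1) {
      keep_beta.row(kept) = beta.t();
      keep_a.row(kept) = a.t();
      keep_b.row(kept) = b.t();
      keep_alpha2[kept] = alpha2;
      if (store_theta) keep_theta.row(kept) = theta.t();
      sum_theta += theta;
      sumsq_theta += arma::square(theta);
      sum_z += z;
      arma::vec r2 = theta - X * beta;
      double ll = -0.5 * n * std::log(2.0 * M_PI * alpha2) -
        0.5 * arma::dot(r2, r2) / alpha2;
      keep_dev[kept] = meas_deviance(Y, z, theta, a, b) - 2.0 * ll;
      keep_dev_obs[kept] = obs_deviance(Y, theta, a, b) - 2.0 * ll;
      ++kept;
    }
  }

  List out = List::create(
    _["beta"] = keep_beta, _["a"] = keep_a, _["b"] = keep_b,
    _["alpha2"] = keep_alpha2, _["deviance"] = keep_dev,
    _["deviance_obs"] = keep_dev_obs,
    _["theta_mean"] = sum_theta / kept,
    _["theta_sd"] = arma::sqrt(arma::clamp(
        sumsq_theta / kept - arma::square(sum_theta / kept), 0.0,
        arma::datum::inf)),
    _["z_mean"] = sum_z / kept);
  if (store_theta) out["theta"] = keep_theta;
  return out;
}
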