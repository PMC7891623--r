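// Metropolis-within-Gibbs sampler for the Gaussian location-scale model
//   y_i ~ N(B_i beta_mu, exp(B_i beta_sigma)^2)
// with Gaussian term priors (optionally scaled by a smoothing variance
// tau^2) and conjugate inverse-gamma updates of the smoothing variances.
//
// The mu block has a Gaussian full conditional (identity link, Gaussian
// likelihood), so it is updated by an exact Gibbs draw. The sigma block is
// updated by a Metropolis-Hastings step with an iteratively weighted least
// squares (IWLS) proposal: Fisher-scoring weight 2 per observation, working
// response z = eta + (r^2 exp(-2 eta) - 1)/2. Because the Fisher weights do
// not depend on the state, the proposal precision is constant within an
// iteration and only the proposal mean moves, which makes the asymmetry
// correction cheap.
//
// All randomness comes from R's RNG so that set.seed() makes runs
// bit-reproducible.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

static const double ETA_BOUND = 20.0;

static arma::vec clamp_eta(const arma::vec& eta) {
  return arma::clamp(eta, -ETA_BOUND, ETA_BOUND);
}

static arma::vec rnorm_vec(int p) {
  arma::vec z(p);
  for (int i = 0; i < p; ++i) z[i] = R::norm_rand();
  return z;
}

// log N(x; mean, (Q/s^2)^{-1}) up to the additive constant shared by
// forward and reverse proposals (logdet(Q) and s are common, so only the
// quadratic form is needed).
static double mvn_quad(const arma::vec& x, const arma::vec& mean,
                       const arma::mat& Q) {
  arma::vec d = x - mean;
  return -0.5 * arma::dot(d, Q * d);
}

// Gaussian log-likelihood in the sigma parametrisation, dropping the
// -n/2 log(2 pi) constant: sum(-eta - 0.5 r^2 exp(-2 eta)).
static double loglik_sigma(const arma::vec& r, const arma::vec& eta) {
  return arma::accu(-eta - 0.5 * arma::square(r) % arma::exp(-2.0 * eta));
}

// quadratic prior kernel (beta - m)' C (beta - m) / (2 tau2_eff)
static double prior_kernel(const arma::vec& beta, const arma::vec& m,
                           const arma::mat& C, double tau2_eff) {
  arma::vec d = beta - m;
  return -0.5 * arma::dot(d, C * d) / tau2_eff;
}

static double draw_inv_gamma(double shape, double rate) {
  // X ~ Gamma(shape, rate) => 1/X ~ IG(shape, rate); R::rgamma takes scale
  double g = R::rgamma(shape, 1.0 / rate);
  if (g <= 0) g = std::numeric_limits<double>::min();
  return 1.0 / g;
}

// [[Rcpp::export(name = ".mcmc_chain_cpp")]]
List mcmc_chain_cpp(const arma::mat& B, const arma::vec& y,
                    const arma::vec& m_mu, const arma::mat& C_mu,
                    bool scaled_mu, double rank_mu,
                    const arma::vec& m_sg, const arma::mat& C_sg,
                    bool scaled_sg, double rank_sg,
                    double ig_a, double ig_b,
                    int n_iter, int n_burnin,
                    arma::vec beta_mu, arma::vec beta_sg,
                    double tau2_mu, double tau2_sg,
                    double step_scale, bool sample_mu_block,
                    bool sample_sg_block, bool sample_tau,
                    const arma::vec& fixed_eta_sg) {
  const int n = B.n_rows, p = B.n_cols;
  const bool have_fixed_eta = fixed_eta_sg.n_elem == (unsigned)n;
  if (have_fixed_eta) sample_sg_block = false;
  const int keep = n_iter - n_burnin;
  if (keep <= 0) stop("n_iter must exceed n_burnin");

  arma::mat BtB = B.t() * B;
  const double jitter = 1e-10 * arma::trace(BtB) / p;
  arma::mat keep_mu(keep, p), keep_sg(keep, p);
  arma::vec keep_t2mu(keep), keep_t2sg(keep);

  int acc_sg_burn = 0, acc_sg_keep = 0, n_sg_burn = 0, n_sg_keep = 0;

  arma::vec eta = have_fixed_eta ? fixed_eta_sg : clamp_eta(B * beta_sg);
  arma::vec sig2 = arma::exp(2.0 * eta);

  for (int it = 0; it < n_iter; ++it) {
    // ---- mu block: exact Gibbs draw from the Gaussian full conditional
    if (sample_mu_block) {
      arma::mat P = scaled_mu ? arma::mat(C_mu / tau2_mu) : C_mu;
      arma::vec w = 1.0 / sig2;
      arma::mat Q = B.t() * (B.each_col() % w) + P;
      Q.diag() += jitter;
      arma::vec rhs = B.t() * (y % w) + P * m_mu;
      arma::mat U = arma::chol(Q);                       // Q = U'U
      arma::vec mean = arma::solve(arma::trimatu(U),
                        arma::solve(arma::trimatl(U.t()), rhs));
      beta_mu = mean + arma::solve(arma::trimatu(U), rnorm_vec(p));
    }

    // ---- sigma block: MH with IWLS proposal (constant Fisher weight 2)
    if (sample_sg_block) {
      arma::vec r = y - B * beta_mu;
      arma::vec eta_cur = clamp_eta(B * beta_sg);
      arma::mat P = scaled_sg ? arma::mat(C_sg / tau2_sg) : C_sg;
      arma::mat Q = 2.0 * BtB + P;
      Q.diag() += jitter;
      arma::mat U = arma::chol(Q);
      arma::vec Pm = P * m_sg;

      arma::vec z = eta_cur +
        0.5 * (arma::square(r) % arma::exp(-2.0 * eta_cur) - 1.0);
      arma::vec rhs_f = 2.0 * (B.t() * z) + Pm;
      arma::vec mean_f = arma::solve(arma::trimatu(U),
                          arma::solve(arma::trimatl(U.t()), rhs_f));
      arma::vec prop = mean_f +
        step_scale * arma::solve(arma::trimatu(U), rnorm_vec(p));

      arma::vec eta_prop = clamp_eta(B * prop);
      arma::vec z_r = eta_prop +
        0.5 * (arma::square(r) % arma::exp(-2.0 * eta_prop) - 1.0);
      arma::vec rhs_r = 2.0 * (B.t() * z_r) + Pm;
      arma::vec mean_r = arma::solve(arma::trimatu(U),
                          arma::solve(arma::trimatl(U.t()), rhs_r));

      double tau2_eff = scaled_sg ? tau2_sg : 1.0;
      double s2 = step_scale * step_scale;
      double log_alpha =
        (loglik_sigma(r, eta_prop) + prior_kernel(prop, m_sg, C_sg, tau2_eff)) -
        (loglik_sigma(r, eta_cur) + prior_kernel(beta_sg, m_sg, C_sg, tau2_eff)) +
        mvn_quad(beta_sg, mean_r, Q) / s2 - mvn_quad(prop, mean_f, Q) / s2;

      bool accepted = std::log(R::unif_rand()) < log_alpha;
      if (accepted) {
        beta_sg = prop;
        eta = eta_prop;
      } else {
        eta = eta_cur;
      }
      sig2 = arma::exp(2.0 * eta);
      if (it < n_burnin) { n_sg_burn++; acc_sg_burn += accepted; }
      else               { n_sg_keep++; acc_sg_keep += accepted; }

      // adaptive fallback: if the IWLS proposal is being rejected almost
      // always midway through burn-in, shrink the proposal spread
      if (it + 1 == n_burnin / 2 && n_sg_burn > 0 &&
          acc_sg_burn < 0.05 * n_sg_burn) {
        step_scale = std::max(0.1, step_scale * 0.5);
      }
    } else if (!have_fixed_eta) {
      eta = clamp_eta(B * beta_sg);
      sig2 = arma::exp(2.0 * eta);
    }

    // ---- smoothing variances: conjugate IG full conditionals
    if (sample_tau) {
      if (scaled_mu) {
        arma::vec d = beta_mu - m_mu;
        tau2_mu = draw_inv_gamma(ig_a + 0.5 * rank_mu,
                                 ig_b + 0.5 * arma::dot(d, C_mu * d));
      } else {
        tau2_mu = draw_inv_gamma(ig_a, ig_b);   // inert: prior draw
      }
      if (scaled_sg) {
        arma::vec d = beta_sg - m_sg;
        tau2_sg = draw_inv_gamma(ig_a + 0.5 * rank_sg,
                                 ig_b + 0.5 * arma::dot(d, C_sg * d));
      } else {
        tau2_sg = draw_inv_gamma(ig_a, ig_b);
      }
    }

    if (it >= n_burnin) {
      int k = it - n_burnin;
      keep_mu.row(k) = beta_mu.t();
      keep_sg.row(k) = beta_sg.t();
      keep_t2mu[k] = tau2_mu;
      keep_t2sg[k] = tau2_sg;
    }
  }

  double acc_rate = n_sg_keep > 0 ? (double)acc_sg_keep / n_sg_keep : NA_REAL;
  return List::create(
    _["beta_mu"] = keep_mu, _["beta_sigma"] = keep_sg,
    _["tau2_mu"] = keep_t2mu, _["tau2_sigma"] = keep_t2sg,
    _["accept_sigma"] = acc_rate,
    _["accept_sigma_burnin"] =
      n_sg_burn > 0 ? (double)acc_sg_burn / n_sg_burn : NA_REAL,
    _["step_scale_final"] = step_scale);
}
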