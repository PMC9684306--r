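#include <Rcpp.h>
using namespace Rcpp;

// One-sided truncated normal draws, robust in the far tail
// (inverse-CDF near the mode, Robert (1995) exponential rejection otherwise).
static double rtnorm_pos(double mu, double sd) {
  // sample from N(mu, sd^2) truncated to (0, Inf)
  double a = -mu / sd; // standardized lower bound
  if (a < 5.0) {
    double pa = R::pnorm(a, 0.0, 1.0, 1, 0);
    double u = R::runif(0.0, 1.0);
    double z = R::qnorm(pa + u * (1.0 - pa), 0.0, 1.0, 1, 0);
    if (R_finite(z) && z > a) return mu + sd * z;
  }
  // tail: exponential rejection on the standardized scale
  double alpha = 0.5 * (a + std::sqrt(a * a + 4.0));
  for (int it = 0; it < 1000; ++it) {
    double z = a + R::rexp(1.0) / alpha;
    double rho = std::exp(-0.5 * (z - alpha) * (z - alpha));
    if (R::runif(0.0, 1.0) <= rho) return mu + sd * z;
  }
  return mu + sd * (a + 1e-8); // unreachable fallback
}

// Draw from density proportional to exp(-0.5*a*b^2 + blin*b - tau*|b|):
// a two-piece truncated-normal mixture.
static double draw_beta_laplace(double a, double blin, double tau) {
  double sd = 1.0 / std::sqrt(a);
  double mu_pos = (blin - tau) / a;
  double mu_neg = (blin + tau) / a;
  // piece log-masses (common constants dropped)
  double lw_pos = 0.5 * a * mu_pos * mu_pos +
    R::pnorm(0.0, mu_pos, sd, 0, 1); // upper tail, log
  double lw_neg = 0.5 * a * mu_neg * mu_neg +
    R::pnorm(0.0, mu_neg, sd, 1, 1); // lower tail, log
  double ppos = 1.0 / (1.0 + std::exp(lw_neg - lw_pos));
  if (R::runif(0.0, 1.0) < ppos) {
    return rtnorm_pos(mu_pos, sd);
  } else {
    return -rtnorm_pos(-mu_neg, sd);
  }
}

// [[Rcpp::export(name = ".bmrf_mcmc")]]
List bmrf_mcmc(NumericMatrix S, int n,
               IntegerMatrix pairs,      // m x 2, zero-based node indices
               NumericVector prior_a, NumericVector prior_b,
               double tau1, double tau0,
               double sig_a0, double sig_b0,
               int n_iter, int burn_in, int thin,
               bool metropolis, double mh_sd,
               bool update_sigma, NumericVector sigma2_init) {
  const int p = S.nrow();
  const int m = pairs.nrow();
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter");
  if (!(tau0 > tau1 && tau1 > 0)) stop("need tau0 > tau1 > 0");

  std::vector<double> beta(m, 0.0), pvec(m), sigma2(p);
  std::vector<int> gamma(m, 0);
  for (int e = 0; e < m; ++e) pvec[e] = prior_a[e] / (prior_a[e] + prior_b[e]);
  for (int j = 0; j < p; ++j) sigma2[j] = sigma2_init[j];

  // B: symmetric strength matrix; T = S %*% B maintained incrementally
  NumericMatrix B(p, p), T(p, p);

  const int n_keep = (n_iter - burn_in + thin - 1) / thin;
  NumericMatrix beta_draws(n_keep, m), p_draws(n_keep, m), sig_draws(n_keep, p);
  IntegerMatrix gamma_draws(n_keep, m);

  RNGScope scope;
  int keep = 0;
  const double log_tau_ratio = std::log(tau1 / tau0);

  for (int it = 0; it < n_iter; ++it) {
    // (i)+(ii)+(iii): per candidate pair, update beta, gamma, p
    for (int e = 0; e < m; ++e) {
      const int j = pairs(e, 0), k = pairs(e, 1);
      const double bOld = beta[e];
      const double tau = gamma[e] ? tau1 : tau0;
      const double a = S(k, k) / sigma2[j] + S(j, j) / sigma2[k];
      // x_k' r_j with the pair's own contribution removed, plus same for rows k
      const double blin =
        (S(j, k) - T(k, j) + bOld * S(k, k)) / sigma2[j] +
        (S(j, k) - T(j, k) + bOld * S(j, j)) / sigma2[k];
      double bNew;
      if (!metropolis) {
        bNew = draw_beta_laplace(a, blin, tau);
      } else {
        // random-walk Metropolis on the same full conditional
        const double prop = bOld + R::rnorm(0.0, mh_sd);
        const double logr =
          (-0.5 * a * prop * prop + blin * prop - tau * std::fabs(prop)) -
          (-0.5 * a * bOld * bOld + blin * bOld - tau * std::fabs(bOld));
        bNew = (std::log(R::runif(0.0, 1.0)) < logr) ? prop : bOld;
      }
      if (!R_finite(bNew))
        stop("divergent chain: non-finite beta at iteration %d", it + 1);
      const double d = bNew - bOld;
      if (d != 0.0) {
        beta[e] = bNew;
        B(j, k) = B(k, j) = bNew;
        for (int i = 0; i < p; ++i) {
          T(i, j) += d * S(i, k);
          T(i, k) += d * S(i, j);
        }
      }
      // gamma | beta, p : Bernoulli with odds p*psi1 / ((1-p)*psi0)
      const double lo = std::log(pvec[e] / (1.0 - pvec[e])) + log_tau_ratio +
        (tau0 - tau1) * std::fabs(beta[e]);
      const double pg = 1.0 / (1.0 + std::exp(-lo));
      gamma[e] = (R::runif(0.0, 1.0) < pg) ? 1 : 0;
      // p | gamma : conjugate Beta
      pvec[e] = R::rbeta(prior_a[e] + gamma[e], prior_b[e] + 1 - gamma[e]);
      if (pvec[e] <= 0.0) pvec[e] = 1e-12;
      if (pvec[e] >= 1.0) pvec[e] = 1.0 - 1e-12;
    }

    // (iv): sigma_j^2 | rest, conjugate inverse-gamma
    if (update_sigma) {
      for (int j = 0; j < p; ++j) {
        double cross = 0.0, quad = 0.0;
        for (int k2 = 0; k2 < p; ++k2) {
          cross += B(j, k2) * S(j, k2);
          quad += B(j, k2) * T(k2, j);
        }
        double rss = S(j, j) - 2.0 * cross + quad;
        if (rss < 0.0) rss = 0.0; // numerical guard
        sigma2[j] = 1.0 / R::rgamma(sig_a0 + 0.5 * n, 1.0 / (sig_b0 + 0.5 * rss));
        if (!R_finite(sigma2[j]) || sigma2[j] <= 0.0)
          stop("divergent chain: invalid sigma2 at iteration %d", it + 1);
      }
    }

    // refresh T from scratch periodically to cap floating-point drift
    if ((it + 1) % 500 == 0) {
      for (int j = 0; j < p; ++j)
        for (int i = 0; i < p; ++i) {
          double s = 0.0;
          for (int k2 = 0; k2 < p; ++k2) s += S(i, k2) * B(k2, j);
          T(i, j) = s;
        }
    }

    if (it >= burn_in && (it - burn_in) % thin == 0) {
      for (int e = 0; e < m; ++e) {
        beta_draws(keep, e) = beta[e];
        gamma_draws(keep, e) = gamma[e];
        p_draws(keep, e) = pvec[e];
      }
      for (int j = 0; j < p; ++j) sig_draws(keep, j) = sigma2[j];
      ++keep;
    }
  }

  return List::create(_["beta"] = beta_draws, _["gamma"] = gamma_draws,
                      _["p"] = p_draws, _["sigma2"] = sig_draws);
}
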