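// Gibbs sampler for Bayesian mixture-prior (spike + K Gaussian slabs)
// regression over standardized features. Single-site conjugate updates with
// residual-vector maintenance give O(n) cost per feature per sweep. All
// randomness comes from R's RNG so set.seed() in R makes runs deterministic.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// categorical draw from unnormalized log-weights
static int sample_category(const arma::vec &logw) {
  double m = logw.max();
  arma::vec w = arma::exp(logw - m);
  double total = arma::accu(w);
  double u = R::unif_rand() * total;
  double cum = 0.0;
  for (arma::uword k = 0; k < w.n_elem; ++k) {
    cum += w(k);
    if (u <= cum) return (int)k;
  }
  return (int)(w.n_elem - 1);
}

// [[Rcpp::export]]
List bayesr_gibbs_cpp(const arma::mat &X, const arma::vec &y,
                      const arma::vec &gamma, int burn_in, int n_store,
                      int thin, double dir_alpha, double nu0, double s02,
                      double fix_sigma2, NumericVector fix_pi) {
  const int n = X.n_rows;
  const int p = X.n_cols;
  const int K = gamma.n_elem;            // slab components; class 0 is the spike
  const bool sigma_fixed = fix_sigma2 > 0.0;
  const bool pi_fixed = fix_pi.size() == K + 1;

  arma::vec xtx(p);
  for (int j = 0; j < p; ++j) xtx(j) = arma::dot(X.col(j), X.col(j));

  arma::vec beta(p, arma::fill::zeros);
  arma::ivec comp(p, arma::fill::zeros);
  arma::vec resid = y;
  double sigma2 = sigma_fixed ? fix_sigma2 : arma::var(y);
  arma::vec pi(K + 1);
  if (pi_fixed) {
    for (int k = 0; k <= K; ++k) pi(k) = fix_pi[k];
  } else {
    pi.fill(1.0 / (K + 1));
  }

  const int total_iter = burn_in + n_store * thin;
  arma::mat beta_out(n_store, p);
  arma::imat comp_out(n_store, p);
  arma::vec sigma2_out(n_store);
  arma::mat pi_out(n_store, K + 1);

  arma::uvec ord = arma::regspace<arma::uvec>(0, p - 1);
  arma::vec logw(K + 1), mu(K + 1), v(K + 1);
  // membership counts persist across sweeps; all effects start in the spike
  arma::ivec counts(K + 1, arma::fill::zeros);
  counts(0) = p;
  int s = 0;

  for (int it = 0; it < total_iter; ++it) {
    // seeded random update order (Fisher-Yates via R's RNG)
    for (int i = p - 1; i > 0; --i) {
      int j = (int)std::floor(R::unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(ord(i), ord(j));
    }
    for (int u = 0; u < p; ++u) {
      const int j = ord(u);
      const double rhs = arma::dot(X.col(j), resid) + xtx(j) * beta(j);
      // membership weights: with pi fixed use it directly; otherwise the
      // mixture proportions are collapsed out (Dirichlet-multinomial urn on
      // the memberships of the other CpGs), which mixes far better than
      // sampling pi explicitly when spike and small slab are near
      // indistinguishable per CpG
      if (pi_fixed) {
        logw(0) = std::log(pi(0));
      } else {
        logw(0) = std::log(dir_alpha + (double)(counts(0) - (comp(j) == 0)));
      }
      for (int k = 1; k <= K; ++k) {
        const double vk = gamma(k - 1);
        const double prec = xtx(j) / sigma2 + 1.0 / vk;
        const double m = (rhs / sigma2) / prec;
        const double lp = pi_fixed
          ? std::log(pi(k))
          : std::log(dir_alpha + (double)(counts(k) - (comp(j) == k)));
        logw(k) = lp - 0.5 * std::log(vk * prec) + 0.5 * m * m * prec;
        mu(k) = m;
        v(k) = 1.0 / prec;
      }
      const int k = sample_category(logw);
      const double bnew = (k == 0) ? 0.0 : R::rnorm(mu(k), std::sqrt(v(k)));
      if (bnew != beta(j)) {
        resid += X.col(j) * (beta(j) - bnew);
        beta(j) = bnew;
      }
      counts(comp(j)) -= 1;
      counts(k) += 1;
      comp(j) = k;
    }
    if (!sigma_fixed) {
      const double ss = arma::dot(resid, resid);
      sigma2 = (nu0 * s02 + ss) / R::rchisq(nu0 + (double)n);
    }
    if (!pi_fixed) {
      // reporting draw of the mixture proportions given the memberships
      double tot = 0.0;
      for (int k = 0; k <= K; ++k) {
        double g = R::rgamma(dir_alpha + (double)counts(k), 1.0);
        if (g <= 0.0) g = 1e-300;
        pi(k) = g;
        tot += g;
      }
      pi /= tot;
    }
    if (it >= burn_in && ((it - burn_in + 1) % thin == 0)) {
      beta_out.row(s) = beta.t();
      for (int j = 0; j < p; ++j) comp_out(s, j) = comp(j);
      sigma2_out(s) = sigma2;
      pi_out.row(s) = pi.t();
      ++s;
    }
  }

  return List::create(
    Named("beta") = beta_out,
    Named("comp") = comp_out,
    Named("sigma2") = sigma2_out,
    Named("pi") = pi_out
  );
}
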