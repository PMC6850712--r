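#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Bartlett draw from Wishart(df, V) with V the scale matrix (E[W] = df * V).
// Uses R's RNG so draws are reproducible under set.seed().
static arma::mat rwishart_bartlett(double df, const arma::mat& V) {
  const arma::uword J = V.n_rows;
  arma::mat L = arma::chol(V, "lower");
  arma::mat A(J, J, arma::fill::zeros);
  for (arma::uword i = 0; i < J; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - static_cast<double>(i)));
    for (arma::uword j = 0; j < i; ++j) A(i, j) = R::rnorm(0.0, 1.0);
  }
  arma::mat X = L * A;
  return X * X.t();
}

// One MCMC chain for the hierarchical multivariate-normal model
//   Y_i | group k ~ MN(mu_k, Sigma),  mu_{j,k} ~ N(0, epsilon),
//   Omega = Sigma^{-1} ~ Wishart(nu0, R0^{-1})  [rate matrix R0]
// alternating the two conjugate blocks. Group labels are 0-based.
// When update_means is false the means stay at mu_init and only the
// precision block is sampled (i.i.d. draws from its closed-form
// conditional), which is the hook used to validate the Wishart update.
// [[Rcpp::export]]
List gibbs_chain(const arma::mat& Y, const arma::ivec& group, int n_groups,
                 int n_iter, int burnin, int thin, double epsilon,
                 const arma::mat& R0, double nu0, const arma::mat& mu_init,
                 const arma::mat& omega_init, bool update_means) {
  const arma::uword N = Y.n_rows, J = Y.n_cols;
  const arma::uword K = static_cast<arma::uword>(n_groups);
  const int n_keep = (n_iter - burnin) / thin;

  // per-group observation sums and sizes
  arma::mat group_sum(K, J, arma::fill::zeros);
  arma::vec group_n(K, arma::fill::zeros);
  for (arma::uword i = 0; i < N; ++i) {
    arma::uword k = static_cast<arma::uword>(group(i));
    group_sum.row(k) += Y.row(i);
    group_n(k) += 1.0;
  }

  arma::mat mu = mu_init;       // K x J
  arma::mat omega = omega_init; // J x J
  arma::cube mu_draws(K, J, n_keep);
  arma::cube sigma_draws(J, J, n_keep);
  arma::cube omega_draws(J, J, n_keep);
  const arma::mat I_J = arma::eye<arma::mat>(J, J);

  int kept = 0;
  for (int t = 1; t <= n_iter; ++t) {
    if (update_means) {
      // mu_k | Omega, Y ~ MN(P^{-1} Omega s_k, P^{-1}), P = n_k Omega + I/eps
      for (arma::uword k = 0; k < K; ++k) {
        arma::mat P = group_n(k) * omega + I_J / epsilon;
        arma::mat Ru = arma::chol(P); // upper: Ru' Ru = P
        arma::vec m = arma::solve(arma::trimatu(Ru),
                       arma::solve(arma::trimatl(Ru.t()),
                                   omega * group_sum.row(k).t()));
        arma::vec z(J);
        for (arma::uword j = 0; j < J; ++j) z(j) = R::rnorm(0.0, 1.0);
        mu.row(k) = (m + arma::solve(arma::trimatu(Ru), z)).t();
      }
    }

    // Omega | mu, Y ~ Wishart(nu0 + N, (R0 + S)^{-1})
    arma::mat S(J, J, arma::fill::zeros);
    for (arma::uword i = 0; i < N; ++i) {
      arma::rowvec d = Y.row(i) - mu.row(static_cast<arma::uword>(group(i)));
      S += d.t() * d;
    }
    arma::mat scale = arma::inv_sympd(arma::symmatu(R0 + S));
    omega = rwishart_bartlett(nu0 + static_cast<double>(N), scale);
    if (!omega.is_finite())
      stop("non-finite precision draw at iteration %d", t);

    if (t > burnin && (t - burnin) % thin == 0) {
      mu_draws.slice(kept) = mu;
      omega_draws.slice(kept) = omega;
      sigma_draws.slice(kept) = arma::inv_sympd(arma::symmatu(omega));
      ++kept;
    }
  }

  return List::create(_["mu"] = mu_draws, _["sigma"] = sigma_draws,
                      _["omega"] = omega_draws);
}
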