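# Fixtures are built in code at test time.

# random symmetric positive-definite matrix with spread eigenvalues
make_spd <- function(j, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- matrix(rnorm(j * j), j, j)
  q <- qr.Q(qr(a))
  q %*% diag(exp(runif(j, -1, 1)), j) %*% t(q)
}

# small grouped dataset with known generating parameters
make_grouped <- function(n_per_group = 10, K = 4, sigma = diag(3),
                         between_var = 0, seed = 1) {
  set.seed(seed)
  J <- ncol(sigma)
  mu <- matrix(rnorm(K * J, 0, sqrt(between_var)), K, J)
  vals <- do.call(rbind, lapply(seq_len(K), function(k)
    MASS::mvrnorm(n_per_group, mu[k, ], sigma)))
  grouped_observations(vals, rep(paste0("g", seq_len(K)), each = n_per_group))
}

# short-but-adequate MCMC settings for unit tests (200 retained per chain)
quick_config <- function(seed = 1, n_chains = 2) {
  fit_config(n_iterations = 3000, n_burnin = 1000, n_chains = n_chains,
             thin = 10, seed = seed)
}

# hand-built ensemble from explicit per-chain draw matrices, for
# diagnostic tests; mu_draws is a list (one per chain) of n x J matrices
fake_ensemble <- function(mu_draws, sigma_base = NULL) {
  J <- ncol(mu_draws[[1]])
  n <- nrow(mu_draws[[1]])
  chains <- lapply(mu_draws, function(m) {
    mu <- array(NA_real_, c(1, J, n))
    sg <- array(NA_real_, c(J, J, n))
    for (i in seq_len(n)) {
      mu[1, , i] <- m[i, ]
      sg[, , i] <- if (is.null(sigma_base)) diag(J) * (1 + 0.1 * sin(i)) else sigma_base
    }
    list(mu = mu, sigma = sg)
  })
  structure(list(model_kind = "empirical",
                 config = fit_config(n_iterations = 2 * n, n_burnin = n,
                                     thin = 1, n_chains = length(mu_draws)),
                 chains = chains, prior = list(nu0 = J + 1, rate = diag(J)),
                 variable_names = paste0("V", seq_len(J)),
                 group_names = "all", centering = NULL),
            class = "hv_ensemble")
}

fixture_csv <- system.file("extdata", "synthetic_grouped_example.csv",
                           package = "mbhv")
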