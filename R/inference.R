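#' MCMC configuration for hypervolume model fits
#'
#' Defaults follow common practice for this model family: 100,000
#' iterations with the first half discarded as burn-in, three chains,
#' thinning by 10, and a fixed prior variance `epsilon = 10000` on the
#' group-level mean intercepts (weakly informative once data are
#' centered; `epsilon` is a constant of the model, not an estimated
#' hyperparameter).
#'
#' Fewer than 100 retained draws per chain is treated as a convergence
#' problem (warned at fit time, surfaced by the CLI as exit code 3)
#' rather than a configuration error, so deliberately short exploratory
#' runs are possible but loudly flagged.
#'
#' @param n_iterations total Gibbs iterations per chain.
#' @param n_burnin iterations discarded; default `floor(n_iterations/2)`.
#' @param n_chains number of chains (>= 2 needed for Gelman-Rubin).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param epsilon prior variance of each group/variable mean intercept.
#' @param seed integer seed; all chains derive from it deterministically.
#' @return A `fit_config` list.
#' @export
fit_config <- function(n_iterations = 100000L,
                       n_burnin = floor(n_iterations / 2),
                       n_chains = 3L, thin = 10L,
                       epsilon = 10000, seed = 1L) {
  n_iterations <- as.integer(n_iterations)
  n_burnin <- as.integer(n_burnin)
  if (n_iterations < 1L) stop_config("n_iterations must be positive")
  if (n_burnin < 0L || n_burnin >= n_iterations)
    stop_config("n_burnin must satisfy 0 <= n_burnin < n_iterations")
  if (n_chains < 1L) stop_config("n_chains must be positive")
  if (thin < 1L) stop_config("thin must be positive")
  if (epsilon <= 0) stop_config("epsilon must be positive")
  structure(list(n_iterations = n_iterations, n_burnin = n_burnin,
                 n_chains = as.integer(n_chains), thin = as.integer(thin),
                 epsilon = epsilon, seed = as.integer(seed)),
            class = "fit_config")
}

retained_per_chain <- function(config) {
  (config$n_iterations - config$n_burnin) %/% config$thin
}

# Shared Gibbs driver. `groups`/`K` already resolved by the caller;
# `prior_rate` is the Wishart rate matrix R0 (default: pooled covariance
# of the data, the "raw-data" prior).
fit_gibbs <- function(data, config, model_kind, groups, K, prior_rate) {
  Y <- data$values
  N <- nrow(Y)
  J <- ncol(Y)
  sds <- apply(Y, 2, sd)
  gm <- colMeans(Y)
  if (any(sds > 0 & abs(gm) > 1e-6 * sds))
    warning("data do not appear to be centered (a grand mean exceeds 1e-6 ",
            "of its column's standard deviation); consider center_observations()",
            call. = FALSE)
  R0 <- prior_rate %||% raw_covariance(data)
  if (!isTRUE(all.equal(R0, t(R0), tolerance = 1e-8)))
    stop_config("prior_rate must be symmetric")
  nu0 <- J + 1
  n_keep <- retained_per_chain(config)
  if (n_keep < 1L) stop_config("no retained draws: increase iterations or reduce thinning")
  if (n_keep < 100L)
    warning(sprintf(
      "only %d retained draws per chain (< 100): chains are under-run and posterior summaries and convergence diagnostics are unreliable",
      n_keep), call. = FALSE)

  # initial values: group sample means / precision at the inverse pooled
  # covariance, but overdispersed across chains (scale factors log-spaced
  # on [0.1, 10]) so the Gelman-Rubin diagnostic starts from distinct
  # points of the parameter space
  mu_hat <- matrix(0, K, J)
  for (k in seq_len(K)) {
    rows <- which(groups == k)
    mu_hat[k, ] <- if (length(rows) == 1L) Y[rows, ] else colMeans(Y[rows, , drop = FALSE])
  }
  ridge <- 1e-8 * mean(diag(R0)) * diag(J)
  omega_hat <- tryCatch(solve(R0), error = function(e) solve(R0 + ridge))
  disp <- if (config$n_chains == 1L) 1 else
    exp(seq(log(0.1), log(10), length.out = config$n_chains))

  set.seed(config$seed)
  chains <- vector("list", config$n_chains)
  for (c_idx in seq_len(config$n_chains)) {
    f <- disp[c_idx]
    mu0 <- mu_hat + if (abs(f - 1) < 1e-12) 0 else
      matrix(rnorm(K * J, sd = rep(sqrt(diag(R0)), each = K)), K, J)
    res <- tryCatch(
      gibbs_chain(Y, as.integer(groups - 1L), as.integer(K),
                  config$n_iterations, config$n_burnin, config$thin,
                  config$epsilon, R0, nu0, mu0, omega_hat / f,
                  TRUE),
      error = function(e)
        stop_mbhv("mbhv_numeric_error", "chain %d failed: %s", c_idx,
                  conditionMessage(e)))
    chains[[c_idx]] <- list(mu = res$mu, sigma = res$sigma)
  }

  structure(
    list(model_kind = model_kind, config = config, chains = chains,
         prior = list(nu0 = nu0, rate = R0),
         variable_names = data$variable_names,
         group_names = if (model_kind == "structured") data$group_names else "all",
         centering = attr(data, "centering", exact = TRUE)),
    class = "hv_ensemble")
}

#' Fit the structured (random-intercept) hypervolume model
#'
#' Gibbs sampler for the hierarchical model in which each group k has its
#' own mean vector, drawn a priori from independent N(0, epsilon), and
#' all groups share a within-group covariance Sigma. The precision
#' Omega = Sigma^-1 carries a Wishart prior with rate matrix equal to the
#' pooled raw-data covariance and degrees of freedom J + 1 (weak). Both
#' full conditionals are conjugate, so the sampler is exact and needs no
#' tuning.
#'
#' @param data a `grouped_obs` object, ideally centered (a warning is
#'   issued otherwise).
#' @param config a [fit_config()].
#' @param prior_rate optional J x J Wishart rate matrix overriding the
#'   pooled raw-data covariance (e.g. to probe the alternative
#'   scale-matrix convention).
#' @return An `hv_ensemble` with per-chain arrays of group-mean draws
#'   (K x J x draws) and covariance draws (J x J x draws).
#' @export
fit_structured <- function(data, config = fit_config(), prior_rate = NULL) {
  stopifnot(inherits(data, "grouped_obs"), inherits(config, "fit_config"))
  fit_gibbs(data, config, "structured", data$groups, n_groups(data), prior_rate)
}

#' Fit the empirical (structure-ignoring) hypervolume model
#'
#' Same likelihood and priors but with all observations pooled into a
#' single group: the posterior covariance then absorbs any between-group
#' spread, which is precisely the bias the structured model corrects.
#'
#' @inheritParams fit_structured
#' @return An `hv_ensemble` with `model_kind = "empirical"` (K = 1).
#' @export
fit_empirical <- function(data, config = fit_config(), prior_rate = NULL) {
  stopifnot(inherits(data, "grouped_obs"), inherits(config, "fit_config"))
  fit_gibbs(data, config, "empirical", rep(1L, nrow(data$values)), 1L, prior_rate)
}

#' @export
print.hv_ensemble <- function(x, ...) {
  d <- dim(x$chains[[1]]$sigma)
  cat(sprintf("%s hypervolume model fit: J = %d, K = %d, %d chain(s) x %d draws\n",
              x$model_kind, d[1], dim(x$chains[[1]]$mu)[1],
              length(x$chains), d[3]))
  invisible(x)
}

ensemble_dims <- function(ensemble) {
  list(K = dim(ensemble$chains[[1]]$mu)[1],
       J = dim(ensemble$chains[[1]]$mu)[2],
       n_keep = dim(ensemble$chains[[1]]$mu)[3],
       n_chains = length(ensemble$chains))
}

#' Per-draw pooled mean vectors
#'
#' For a structured fit the overall centre of the hypervolume is the
#' unweighted average over groups of the group means, computed per draw;
#' for an empirical fit the single mean vector is returned unchanged.
#'
#' @param ensemble an `hv_ensemble`.
#' @return A (total draws) x J matrix, chains concatenated in order.
#' @export
pooled_mean <- function(ensemble) {
  stopifnot(inherits(ensemble, "hv_ensemble"))
  do.call(rbind, lapply(ensemble$chains, function(ch) {
    t(apply(ch$mu, 3, colMeans))
  }))
}

#' Covariance draws as a single array
#'
#' @param ensemble an `hv_ensemble`.
#' @return A J x J x (total draws) array, chains concatenated.
#' @export
sigma_draws <- function(ensemble) {
  stopifnot(inherits(ensemble, "hv_ensemble"))
  d <- ensemble_dims(ensemble)
  arr <- array(NA_real_, c(d$J, d$J, d$n_keep * d$n_chains))
  for (i in seq_along(ensemble$chains))
    arr[, , (i - 1) * d$n_keep + seq_len(d$n_keep)] <- ensemble$chains[[i]]$sigma
  arr
}

# draws as a (n_keep x n_params) matrix per chain; parameters are each
# mu[k,j] followed by the upper triangle of sigma
chain_param_matrix <- function(chain) {
  K <- dim(chain$mu)[1]; J <- dim(chain$mu)[2]; n <- dim(chain$mu)[3]
  mu_flat <- t(apply(chain$mu, 3, as.vector))          # n x (K*J)
  if (K * J == 1L) mu_flat <- matrix(mu_flat, ncol = 1L)
  ut <- which(upper.tri(diag(J), diag = TRUE))
  sg_flat <- t(apply(chain$sigma, 3, function(s) s[ut]))
  if (length(ut) == 1L) sg_flat <- matrix(sg_flat, ncol = 1L)
  idx <- expand.grid(k = seq_len(K), j = seq_len(J))
  sidx <- which(upper.tri(diag(J), diag = TRUE), arr.ind = TRUE)
  out <- cbind(mu_flat, sg_flat)
  colnames(out) <- c(sprintf("mu[%d,%d]", idx$k, idx$j),
                     sprintf("sigma[%d,%d]", sidx[, 1], sidx[, 2]))
  out
}

#' Gelman-Rubin potential scale reduction factors
#'
#' Classic (non-split, non-rank-normalized) R-hat from the between- and
#' within-chain variances, for every scalar parameter: each group mean
#' mu\[k,j\] and each upper-triangular element of Sigma. Values near 1
#' indicate the chains are sampling the same distribution; the
#' conventional warning threshold is 1.1.
#'
#' @param ensemble an `hv_ensemble` fitted with at least two chains.
#' @return Named numeric vector of R-hat values.
#' @export
gelman_rubin <- function(ensemble) {
  stopifnot(inherits(ensemble, "hv_ensemble"))
  m <- length(ensemble$chains)
  if (m < 2L)
    stop_diagnostic("Gelman-Rubin needs >= 2 chains; refit with n_chains >= 2")
  mats <- lapply(ensemble$chains, chain_param_matrix)
  n <- nrow(mats[[1]])
  means <- sapply(mats, colMeans)                    # params x m
  vars <- sapply(mats, function(x) apply(x, 2, var)) # params x m
  if (is.null(dim(means))) { means <- matrix(means, nrow = 1); vars <- matrix(vars, nrow = 1) }
  W <- rowMeans(vars)
  B <- n * apply(means, 1, var)
  var_plus <- (n - 1) / n * W + B / n
  rhat <- sqrt(var_plus / W)
  rhat[W == 0 & B == 0] <- 1
  names(rhat) <- colnames(mats[[1]])
  rhat
}

#' Convergence assessment of a fitted ensemble
#'
#' Combines the Gelman-Rubin diagnostic (threshold `rhat_max`) with a
#' guard on the number of retained draws per chain: short runs cannot
#' support reliable summaries or diagnostics regardless of R-hat.
#'
#' @param ensemble an `hv_ensemble`.
#' @param rhat_max warning threshold for R-hat (conventional 1.1).
#' @return List with `converged` (logical), `rhat` (vector or NULL for
#'   single-chain fits), `flagged` (names of parameters over threshold),
#'   and `n_retained`.
#' @export
check_convergence <- function(ensemble, rhat_max = 1.1) {
  stopifnot(inherits(ensemble, "hv_ensemble"))
  n_keep <- ensemble_dims(ensemble)$n_keep
  rhat <- if (length(ensemble$chains) >= 2L) gelman_rubin(ensemble) else NULL
  flagged <- if (is.null(rhat)) character(0) else names(rhat)[rhat >= rhat_max]
  list(converged = n_keep >= 100L && length(flagged) == 0L,
       rhat = rhat, flagged = flagged, n_retained = n_keep)
}

#' Posterior summary table
#'
#' Mean, standard deviation and central 95% interval for each scalar
#' parameter, pooling all chains; the posterior-mean covariance (a mean
#' of symmetric positive-definite matrices, hence itself SPD) and the
#' pooled posterior-mean centre are attached as attributes
#' `mean_sigma` and `mean_mu`.
#'
#' @param ensemble an `hv_ensemble`.
#' @return A data frame with one row per parameter.
#' @export
posterior_summary <- function(ensemble) {
  stopifnot(inherits(ensemble, "hv_ensemble"))
  all_draws <- do.call(rbind, lapply(ensemble$chains, chain_param_matrix))
  tab <- data.frame(
    parameter = colnames(all_draws),
    mean = colMeans(all_draws),
    sd = apply(all_draws, 2, sd),
    q2.5 = apply(all_draws, 2, quantile, probs = 0.025, names = FALSE),
    q97.5 = apply(all_draws, 2, quantile, probs = 0.975, names = FALSE),
    row.names = NULL, stringsAsFactors = FALSE
  )
  d <- ensemble_dims(ensemble)
  sg <- sigma_draws(ensemble)
  attr(tab, "mean_sigma") <- apply(sg, c(1, 2), mean)
  attr(tab, "mean_mu") <- colMeans(pooled_mean(ensemble))
  tab
}
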