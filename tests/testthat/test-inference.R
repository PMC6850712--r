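test_that("fit_config validates and derives defaults", {
  cfg <- fit_config()
  expect_equal(cfg$n_burnin, 50000L)
  expect_equal(cfg$epsilon, 10000)
  expect_error(fit_config(100, n_burnin = 100), class = "mbhv_config_error")
  expect_error(fit_config(0), class = "mbhv_config_error")
  expect_error(fit_config(100, epsilon = -1), class = "mbhv_config_error")
})

test_that("precision draws match the closed-form Wishart conditional", {
  # with group means held fixed the precision conditional is exact:
  # Omega ~ Wishart(nu0 + N, (R0 + S)^-1), so the empirical mean of the
  # sampler's draws must sit within Monte-Carlo error of its mean
  d <- make_grouped(n_per_group = 10, K = 3, sigma = make_spd(3, 11), seed = 2)
  cd <- center_observations(d)$data
  Y <- cd$values
  N <- nrow(Y); J <- ncol(Y)
  mu_fixed <- do.call(rbind, lapply(1:3, function(k)
    colMeans(Y[cd$groups == k, ])))
  R0 <- raw_covariance(cd)
  nu0 <- J + 1
  S <- matrix(0, J, J)
  for (i in seq_len(N)) {
    dd <- Y[i, ] - mu_fixed[cd$groups[i], ]
    S <- S + tcrossprod(dd)
  }
  n_draws <- 5000L
  set.seed(99)
  res <- mbhv:::gibbs_chain(Y, as.integer(cd$groups - 1L), 3L,
                            n_draws, 0L, 1L, 10000, R0, nu0,
                            mu_fixed, solve(R0), FALSE)
  omega_mean <- apply(res$omega, c(1, 2), mean)
  omega_se <- apply(res$omega, c(1, 2), sd) / sqrt(n_draws)
  expected <- (nu0 + N) * solve(R0 + S)
  expect_true(all(abs(omega_mean - expected) < 3 * omega_se))

  # cross-check my Bartlett construction against stats::rWishart moments
  set.seed(7)
  ref <- apply(stats::rWishart(n_draws, nu0 + N, solve(R0 + S)),
               c(1, 2), mean)
  expect_equal(unname(omega_mean), unname(ref), tolerance = 0.05)
})

test_that("sampling is deterministic given the seed and config", {
  d <- center_observations(make_grouped(seed = 3, between_var = 0.5))$data
  f1 <- fit_structured(d, quick_config(seed = 21))
  f2 <- fit_structured(d, quick_config(seed = 21))
  expect_identical(f1$chains, f2$chains)
  f3 <- fit_structured(d, quick_config(seed = 22))
  expect_false(identical(f1$chains, f3$chains))
})

test_that("every retained covariance draw is symmetric positive definite", {
  d <- center_observations(make_grouped(seed = 4, between_var = 1))$data
  fit <- fit_structured(d, quick_config(seed = 31))
  sg <- sigma_draws(fit)
  for (i in seq(1, dim(sg)[3], by = 17)) {
    s <- sg[, , i]
    expect_equal(s, t(s), tolerance = 1e-10)
    expect_no_error(chol(s))
  }
})

test_that("with no between-group spread the posterior covariance converges on the generating matrix", {
  sig <- make_spd(3, 13)
  set.seed(50)
  vals <- MASS::mvrnorm(500, rep(0, 3), sig)
  d <- center_observations(
    grouped_observations(vals, rep(paste0("g", 1:4), length.out = 500)))$data
  fit <- fit_structured(d, quick_config(seed = 41))
  post_sigma <- attr(posterior_summary(fit), "mean_sigma")
  expect_lt(max(abs(post_sigma - sig)) / max(abs(sig)), 0.10)
})

test_that("the empirical fit recovers the pooled covariance on i.i.d. data", {
  set.seed(60)
  vals <- MASS::mvrnorm(500, rep(0, 3), make_spd(3, 17))
  d <- center_observations(
    grouped_observations(vals, rep(1:2, each = 250)))$data
  sr <- raw_covariance(d)
  fit <- fit_empirical(d, quick_config(seed = 51))
  post_sigma <- attr(posterior_summary(fit), "mean_sigma")
  expect_lt(max(abs(post_sigma - sr)) / max(abs(sr)), 0.10)
})

test_that("the empirical fit absorbs between-group spread into the covariance", {
  # law of total variance: pooled per-variable variance tends to
  # diag(Sigma_true) + sigma2_b
  sig <- exchangeable_cov(3, 0.5)
  d <- center_observations(
    make_grouped(n_per_group = 50, K = 10, sigma = sig, between_var = 2,
                 seed = 6))$data
  fit <- fit_empirical(d, quick_config(seed = 61))
  post_sigma <- attr(posterior_summary(fit), "mean_sigma")
  expect_true(all(diag(post_sigma) > diag(sig)))
})

test_that("the structured fit beats the pooled covariance under grouping", {
  # posterior-mean Sigma closer to Sigma_true than Sigma_R (Frobenius)
  # in at least 90% of seeded replicates
  sig <- exchangeable_cov(3, 0.5)
  wins <- vapply(1:50, function(r) {
    d <- center_observations(
      make_grouped(n_per_group = 10, K = 4, sigma = sig, between_var = 2,
                   seed = 1000 + r))$data
    fit <- fit_structured(d, fit_config(2000, 500, 1, 5, seed = r))
    post_sigma <- attr(posterior_summary(fit), "mean_sigma")
    frob <- function(m) sqrt(sum(m^2))
    frob(post_sigma - sig) < frob(raw_covariance(d) - sig)
  }, logical(1))
  expect_gte(mean(wins), 0.90)
})

test_that("a tiny epsilon shrinks all group means to zero", {
  d <- center_observations(make_grouped(seed = 8, between_var = 1))$data
  cfg <- quick_config(seed = 71)
  cfg$epsilon <- 1e-8
  fit <- fit_structured(d, cfg)
  expect_lt(max(abs(pooled_mean(fit))), 1e-3)
  # and the covariance then matches the empirical fit's covariance
  fe <- fit_empirical(d, quick_config(seed = 72))
  s1 <- attr(posterior_summary(fit), "mean_sigma")
  s2 <- attr(posterior_summary(fe), "mean_sigma")
  expect_equal(s1, s2, tolerance = 0.1)
})

test_that("with a single group the structured and empirical fits coincide", {
  set.seed(80)
  d <- center_observations(
    grouped_observations(MASS::mvrnorm(40, rep(0, 3), diag(3)),
                         rep("only", 40)))$data
  fs <- fit_structured(d, quick_config(seed = 81))
  fe <- fit_empirical(d, quick_config(seed = 81))
  expect_identical(fs$chains, fe$chains)
  expect_equal(fs$model_kind, "structured")
  expect_equal(fe$model_kind, "empirical")
})

test_that("pooled_mean averages group means per draw", {
  e <- fake_ensemble(list(matrix(0, 4, 2)))
  # overwrite with a K = 2 structured-style ensemble
  mu <- array(NA_real_, c(2, 3, 2))
  mu[, , 1] <- rbind(c(1, 0, 0), c(3, 2, -2))
  mu[, , 2] <- rbind(c(0, 0, 0), c(0, 0, 0))
  sg <- array(rep(diag(3), 2), c(3, 3, 2))
  e$chains <- list(list(mu = mu, sigma = sg))
  pm <- pooled_mean(e)
  expect_equal(pm[1, ], c(2, 1, -1))
  expect_equal(pm[2, ], c(0, 0, 0))
  # K = 1 is the identity
  e1 <- fake_ensemble(list(rbind(c(1, 2), c(3, 4))))
  expect_equal(pooled_mean(e1), rbind(c(1, 2), c(3, 4)))
})

test_that("uncentered data triggers a warning", {
  d <- make_grouped(seed = 10)
  d$values <- d$values + 5
  expect_warning(fit_structured(d, quick_config()), "centered")
})

test_that("posterior inference is insensitive to the Wishart rate-matrix convention", {
  # rate = Sigma_R (adopted) vs rate = Sigma_R^-1 (the alternative
  # reading): with nu0 = J + 1 the prior is weak, so at moderate N the
  # two posteriors should agree closely
  set.seed(90)
  d <- center_observations(
    make_grouped(n_per_group = 50, K = 4, sigma = make_spd(3, 23),
                 between_var = 1, seed = 12))$data
  f1 <- fit_structured(d, quick_config(seed = 91))
  f2 <- fit_structured(d, quick_config(seed = 91),
                       prior_rate = solve(raw_covariance(d)))
  s1 <- attr(posterior_summary(f1), "mean_sigma")
  s2 <- attr(posterior_summary(f2), "mean_sigma")
  expect_lt(max(abs(s1 - s2)) / max(abs(s1)), 0.05)
})
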