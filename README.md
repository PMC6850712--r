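# mbhv — model-based hypervolumes for grouped multivariate data

`mbhv` estimates parametric ecological hypervolumes — 95% confidence
ellipsoids of a multivariate normal — from data with grouped or nested
structure (plots in survey squares, sites in regions). When such
structure is ignored, the pooled covariance mixes within-group
covariance with the scatter of group means, and the resulting
hypervolume is systematically too large. `mbhv` fits a hierarchical
random-intercept model instead and builds the hypervolume from the
shared **within-group** covariance.

It is aimed at ecologists and biostatisticians who want niche- or
ecosystem-property hypervolumes from structured survey data, with
honest uncertainty propagation.

## The model

For unit *i*, variable *j* = 1..J and group *k* = 1..K:

    Y[i, ,k] ~ MN(mu[ ,k], Sigma)        (shared J x J covariance)
    mu[j,k]  ~ N(0, epsilon)             (epsilon fixed at 10,000)

The precision `Omega = Sigma^-1` carries a Wishart prior with rate
matrix `Sigma_R` (the pooled raw-data covariance) and `J + 1` degrees of
freedom. Both full conditionals are conjugate, so the model is fitted by
an exact, tuning-free two-block Gibbs sampler (compiled with
RcppArmadillo). The "empirical" variant — the same model with K = 1 —
is what conventional multivariate-normal hypervolumes estimate; its
covariance converges on `Sigma_R`.

From a fit (or any mean/covariance pair) the package computes:

- **volume and semi-axes** of the level-`c` ellipsoid:
  `U_J * c^(J/2) * sqrt(det Sigma)`;
- **probability of inclusion** of new observations, Monte-Carlo or via
  its analytic chi-square limit, optionally summarised over all
  posterior draws;
- **overlap and directional containment** of two hypervolumes, by
  simulating points inside each ellipsoid and testing membership in the
  other;
- a **simulation-study engine** measuring the relative volume error
  `(estimated - true) / true` of both estimators on data generated with
  known covariance and controllable between-group variance.

## Worked example

The packaged CSV is a synthetic dataset of 60 observations of three
variables in four groups, generated by the package's own simulator
(between-group variance 1, exchangeable within-group correlation 0.5;
regenerate it with `cmd_fixtures()`).

```r
library(mbhv)

csv <- system.file("extdata", "synthetic_grouped_example.csv", package = "mbhv")
dat <- load_grouped_csv(csv, c("V1", "V2", "V3"), "group")
dat
#> Grouped observations: N = 60, J = 3, K = 4
#> variables: V1, V2, V3
#> group sizes: 15, 15, 15, 15

cen  <- center_observations(dat)
fit  <- fit_structured(cen$data, fit_config(10000, 5000, n_chains = 3,
                                            thin = 5, seed = 1))
femp <- fit_empirical(cen$data, fit_config(10000, 5000, n_chains = 3,
                                           thin = 5, seed = 2))

max(gelman_rubin(fit))     # 1.002  -- all chains agree (threshold 1.1)
mean(volume_draws(fit))    # 47.9   -- model-based volume
mean(volume_draws(femp))   # 156.2  -- pooled volume, inflated ~3x by group shifts

# is the (uncentered) origin inside the fitted hypervolume?
inclusion_probability_posterior(fit, apply_centering(cen$transform, c(0, 0, 0)))
#> inclusion: p = 0.7827 (q = 0.0722, threshold 0.05) -> inside

hv_overlap(as_hypervolume(fit), as_hypervolume(femp), n_points = 50000, seed = 3)
#> overlap = 0.8168 (A in B: 1.0000, B in A: 0.6337; n = 50000 per volume, mc_se = 0.0012)
```

The model-based hypervolume sits entirely inside the inflated empirical
one (containment A in B = 1), which contains substantial regions the
within-group process never visits — the geometry the hierarchical model
exists to correct. `posterior_summary(fit)` tabulates every parameter's
posterior mean, sd and 95% interval.

## Command line

A thin dispatcher over the same functions ships in `inst/cli/mbhv`:

```sh
Rscript inst/cli/mbhv fit --data plots.csv --variables sla,height,nectar \
    --group square --model structured --out fit_heath --seed 1
Rscript inst/cli/mbhv compare --a fit_heath/ensemble.json \
    --b fit_conifer/ensemble.json --out compare.json --seed 1
Rscript inst/cli/mbhv include --archive fit_heath/ensemble.json \
    --archive-b fit_conifer/ensemble.json --points transitions.csv --out inc.csv
Rscript inst/cli/mbhv simulate --config grid.yaml --out simout
```

Exit codes: 0 success, 2 validation error, 3 fit written but flagged by
the convergence check. Every output directory contains a `manifest.json`
with the seed, software version and input digests; fits store their
centering transform and apply it to new points automatically.

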