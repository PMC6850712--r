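---
title: "Model-based hypervolumes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based hypervolumes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbhv)
```

## The problem

Ecologists increasingly summarise multivariate system state as a
*hypervolume*: an n-dimensional region describing the joint distribution
of several measured variables (niche axes, ecosystem properties).
A convenient parametric choice is the 95% confidence ellipsoid of a
multivariate normal — interpretable axes, no orthogonality requirement,
and closed-form geometry.

Real survey data, however, are rarely a simple random sample. Plots are
nested in squares, sites in regions, samples in campaigns. When
observations are grouped, the pooled covariance mixes two different
things: the covariance *within* groups (often the quantity of
scientific interest, reflecting a shared underlying process) and the
scatter of group means. A hypervolume built on pooled data therefore
inflates as soon as group means differ.

`mbhv` separates the two with a hierarchical random-intercept model and
builds the hypervolume from the *within-group* covariance.

## The model

Observations $Y_{i,j,k}$ (unit $i$, variable $j = 1..J$, group
$k = 1..K$) follow

$$Y_{i,\cdot,k} \sim \mathrm{MN}(\mu_{\cdot,k},\ \Sigma), \qquad
  \mu_{j,k} \sim \mathrm{N}(0,\ \varepsilon),$$

with a single covariance $\Sigma$ shared across groups. No overall
per-variable mean is estimated; the fixed, large prior variance
$\varepsilon$ absorbs variability of means across both groups and
variables. This makes $\varepsilon$ itself hard to interpret, but it
guarantees the within-group covariance of interest lands in $\Sigma$.
The *empirical* (structure-ignoring) variant is the same model with
$K = 1$; its $\Sigma$ converges on the pooled sample covariance
$\Sigma_R$.

The precision $\Omega = \Sigma^{-1}$ has a Wishart prior with rate
matrix $R_0 = \Sigma_R$ and degrees of freedom $\nu_0 = J + 1$ — the
weakest proper choice, anchored at the scale of the data. Because both
full conditionals are conjugate,

- $\mu_{\cdot,k} \mid \Omega, Y \sim \mathrm{MN}\!\big(P_k^{-1}\Omega s_k,\ P_k^{-1}\big)$
  with $P_k = n_k\Omega + \varepsilon^{-1}I$ and $s_k$ the within-group
  sum of observations,
- $\Omega \mid \mu, Y \sim \mathrm{Wishart}\!\big(\nu_0 + N,\ (R_0 + S)^{-1}\big)$
  with $S$ the within-group scatter around the current means,

the sampler is an exact two-block Gibbs sampler implemented natively
(in compiled code, drawing the Wishart via the Bartlett decomposition
on R's RNG stream), with no tuning parameters and no external MCMC
runtime. Correctness of the Wishart block is checked in the test suite
by holding the means fixed and comparing the empirical moment of the
precision draws with the closed-form posterior mean
$(\nu_0 + N)(R_0 + S)^{-1}$.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `epsilon` | 10 000 | fixed prior variance of each $\mu_{j,k}$ (dimension of a variable's variance; weakly informative once data are centred) |
| `n_iterations` / `n_burnin` | 100 000 / half | chain length; the default burn-in ratio mirrors the long-run defaults |
| `n_chains` | 3 | $\ge 2$ needed for Gelman-Rubin |
| `thin` | 10 | memory control; the conjugate sampler has low autocorrelation, so thinning costs little information |
| `level` | 0.95 | confidence level of the ellipsoid |

Data should be centred first (`center_observations()`): the
$\mathrm{N}(0, \varepsilon)$ prior is centred at zero, and centring
improves numerical behaviour. Centring is global (grand mean per
variable), not per group — group shifts are exactly what the random
intercepts must absorb. When two datasets are to be compared in one
space, apply one shared transform to both (the transform object is
exposed, and the CLI stores it in the fit archive and applies it to new
points automatically). Variables are not standardised by default; an
optional flag rescales to unit variance, but that changes the units of
the volume.

### Initialisation

Chains start at the group sample means and the inverse pooled
covariance. Across chains the initial covariance scale is overdispersed
(factors log-spaced on $[0.1, 10]$; with three chains the middle one
starts exactly at the data-derived values, and group-mean starts are
jittered on the non-central chains). Overdispersed starting points are
a precondition for the Gelman-Rubin diagnostic to be informative;
starting every chain at the same point would make $\hat R \approx 1$
true by construction. Because the sampler is conjugate it forgets its
start within a few iterations, so this costs nothing at the default
chain lengths.

### Convergence reporting

`gelman_rubin()` implements the classic between/within-chain
$\hat R$ for every scalar parameter (each $\mu_{j,k}$, each
upper-triangular $\Sigma$ element); the warning threshold is the
conventional 1.1. `check_convergence()` additionally flags fits that
retain fewer than 100 draws per chain: a deliberately short run is
reported as a convergence problem (CLI exit code 3) rather than a hard
error, because the outputs may still be useful for exploration while
being unreliable for inference. With an exact conjugate sampler a short
run is typically *mixed* but under-sampled — too few draws for stable
summaries or a meaningful $\hat R$ — which is why the retained-draw
guard, not $\hat R$ alone, drives the warning.

## Hypervolume geometry

With eigenvalues $\lambda_1..\lambda_J$ of $\Sigma$ and
$c = \chi^2_J(\text{level})$:

- semi-axes $\sqrt{\lambda_i c}$, volume
  $U_J\, c^{J/2} \sqrt{\det\Sigma}$ with
  $U_J = \pi^{J/2}/\Gamma(J/2+1)$;
- probability of inclusion of a new point: its density ordering equals
  its Mahalanobis ordering, so the Monte-Carlo test (fraction of
  simulated observations with lower density) has the analytic limit
  $p = 1 - F_{\chi^2_J}(d^2)$. Both are provided; the Monte-Carlo
  version exists because it generalises to summaries over posterior
  draws and is validated against the analytic form in the tests;
- overlap: points are simulated from each hypervolume and tested for
  membership in the other; overlap = shared points / total simulated,
  with both directional containments reported.

Two conventions are deliberate:

1. **Sampling is truncated to the ellipsoid.** "The hypervolume" is the
   ellipsoid, so identical hypervolumes overlap at exactly 1.
   Untruncated sampling (available via `truncate = FALSE`) would cap
   self-overlap near the confidence level.
2. **Membership uses the analytic ellipsoid test**, not a nested
   Monte-Carlo inclusion test: the decision boundary is identical and
   one Monte-Carlo layer of noise (and cost) is removed.

Ties in the density comparison count as "more extreme" — a
probability-zero event fixed for determinism. Both hypervolumes in an
overlap computation are sampled from the same seed, making
`hv_overlap(a, b)` and `hv_overlap(b, a)` exactly symmetric.

### Point estimates under posterior uncertainty

The volume is a nonlinear functional of $\Sigma$, so the package's
point estimate is the **posterior mean of per-draw volumes**
(`volume_draws()`), not the volume of the posterior-mean $\Sigma$
(`as_hypervolume()` provides the latter; the CLI reports both). For
inclusion, the per-draw probabilities are summarised by their mean (or
median), with the per-draw vector returned for interval reporting.
Overlap defaults to the posterior-mean hypervolumes, since a per-draw
overlap multiplies the Monte-Carlo cost by the ensemble size.

## The simulation study

`simulation_scenario()` + `run_scenario()`/`run_grid()` replicate the
estimator-bias experiment: grouped data are generated from the model
itself (group means i.i.d. $\mathrm{N}(0, \sigma^2_b)$ per variable and
group, observations $\mathrm{MN}(\mu_k, s_k\Sigma_{\text{true}})$),
both estimators are fitted, and each fit's volume is compared with the
volume of $\Sigma_{\text{true}}$ via the relative error
$(\hat V - V)/V$.

Generator defaults define the study conditions:

- $\Sigma_{\text{true}}$: unit variances, exchangeable correlation 0.5
  — a simple matrix with real covariance structure; tests also exercise
  diagonal and randomly rotated anisotropic choices;
- design grid $J \in 3..7$, $K \in 4..10$, $n \in 10..50$,
  $\sigma^2_b \in [0, 2]$ (values outside are allowed with a warning);
- group means are redrawn fresh in every replicate;
- unequal-variance violation: per-group covariance multipliers evenly
  spaced on $[0.5, 2]$ — a 4-fold violation of the shared-variance
  assumption;
- replicates per cell: 50 at the desk scale (the full study used 500);
  with 50 replicates the median relative errors are stable to within a
  few hundredths, which is an order of magnitude below the effects
  being measured;
- MCMC inside the study: 10 000 iterations, 5 000 burn-in, 2 chains,
  thinning 5 — 1 000 retained draws per chain from an exact sampler.
  Replicates whose diagnostics fail are excluded from medians and
  counted.

At the three-dimensional, four-group, ten-observation cell this
reproduces the qualitative result: with $\sigma^2_b = 2$ the empirical
estimator's median relative volume error is around +2 (i.e. threefold
overestimation) while the model-based median stays within a few percent
of zero; at $\sigma^2_b = 0$ both methods agree and slightly
underestimate (an exact-sampler, finite-sample effect: the posterior
mean of $\sqrt{\det\Sigma}$ sits slightly below the plug-in value at
$N = 40$). The empirical bias is monotone in $\sigma^2_b$, and under
the unequal-variance violation the model-based median absolute error
stays far below the empirical one. These statements are exactly what
`tests/testthat/test-acceptance.R` verifies and what
`scripts/acceptance.R` recomputes.

### What the generator does *not* emulate

Real ecological data are rarely exactly multivariate normal (skewed
indices, zero-inflation), groups may differ in more than their means,
and group membership can be uncertain. Passing the simulation study
therefore shows correct behaviour *under the model's assumptions* and
robustness to one specific violation (unequal within-group variances);
it does not certify behaviour under non-normality — for that, the
model-based hypervolume shares the limits of any Gaussian method.

## Numerical choices and degenerate inputs

- Sample covariance uses the $N - 1$ denominator; a pooled covariance
  whose smallest eigenvalue is $\le 10^{-10}$ of the largest is
  rejected (it must serve as a Wishart rate matrix).
- The Wishart rate-matrix convention is $R_0 = \Sigma_R$. The source
  description admits two readings ($\Sigma_R$ or its inverse as the
  "scale"); with $\nu_0 = J + 1$ the prior is weak and a test measures
  the consequence — posterior-mean $\Sigma$ under the two conventions
  agrees to within a few percent at moderate $N$. The alternative is
  available via `prior_rate = solve(raw_covariance(data))`.
- Missing values are rejected, not imputed: the model has no
  missingness mechanism.
- CSV output writes 17 significant digits so write/read round-trips are
  exact; ensemble archives are JSON at full precision.
- Seed policy: every stochastic entry point takes a seed; fits derive
  all chains from `config$seed`, and the simulation engine derives
  per-replicate data and fit seeds from the scenario seed, so any
  replicate is reproducible in isolation.

## Known limitations

- Non-normal likelihoods (e.g. Gaussian copulas), temporal
  autocorrelation, crossed random effects and estimation of
  $\varepsilon$ are out of scope.
- Exact ellipsoid–ellipsoid intersection volumes are not computed;
  overlap is Monte-Carlo with a reported standard error.
- Beyond $J \approx 7$–10 dimensions the data demands grow quickly
  (curse of dimensionality) and the method has not been evaluated.

## A worked example

```{r example, eval = FALSE}
library(mbhv)

csv <- system.file("extdata", "synthetic_grouped_example.csv", package = "mbhv")
dat <- load_grouped_csv(csv, c("V1", "V2", "V3"), "group")
cen <- center_observations(dat)

fit  <- fit_structured(cen$data, fit_config(10000, 5000, n_chains = 3,
                                            thin = 5, seed = 1))
femp <- fit_empirical(cen$data, fit_config(10000, 5000, n_chains = 3,
                                           thin = 5, seed = 2))

max(gelman_rubin(fit))              # expect < 1.1
mean(volume_draws(fit))             # model-based volume
mean(volume_draws(femp))            # pooled volume (inflated under grouping)

hv <- as_hypervolume(fit)
inclusion_probability_posterior(fit, apply_centering(cen$transform, c(0, 0, 0)))
hv_overlap(hv, as_hypervolume(femp), n_points = 50000, seed = 3)
```
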