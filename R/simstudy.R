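#' Default within-group covariance for simulations
#'
#' Unit variances with exchangeable correlation `rho` (default 0.5): a
#' simple SPD matrix with genuine covariance structure for the
#' hypervolume to recover.
#'
#' @param n_dims dimension J.
#' @param rho common correlation, in (-1/(J-1), 1).
#' @return A J x J SPD matrix.
#' @export
exchangeable_cov <- function(n_dims, rho = 0.5) {
  if (rho <= -1 / (n_dims - 1) || rho >= 1)
    stop_config("rho = %g gives a non-positive-definite matrix for J = %d",
                rho, n_dims)
  m <- matrix(rho, n_dims, n_dims)
  diag(m) <- 1
  m
}

#' Define one cell of the estimator-bias simulation design
#'
#' Grouped multivariate-normal data are generated with group-mean shifts
#' of variance `between_var` per variable and shared within-group
#' covariance `within_cov` (optionally scaled per group to violate the
#' equal-variance assumption). The design grid of the accompanying
#' simulation study spans J in 3..7, K in 4..10, n in 10..50 and
#' between-group variance 0..2; values outside those ranges are allowed
#' but flagged with a warning.
#'
#' @param n_dims number of variables J.
#' @param n_groups number of groups K.
#' @param n_per_group observations per group.
#' @param between_var variance of group mean shifts (sigma^2_b).
#' @param within_cov J x J SPD within-group covariance Sigma_true;
#'   default [exchangeable_cov()] with rho = 0.5.
#' @param group_scale optional length-K positive multipliers of the
#'   within-group covariance (unequal-variance violation); default all 1.
#' @param n_reps replicate datasets per cell (500 in the full study; 50
#'   is a practical desk default).
#' @param seed integer seed; replicate r uses `seed + r` for data
#'   generation, so cells are reproducible rep by rep.
#' @return A `sim_scenario` object.
#' @export
simulation_scenario <- function(n_dims = 3L, n_groups = 4L, n_per_group = 10L,
                                between_var = 0, within_cov = NULL,
                                group_scale = NULL, n_reps = 50L, seed = 1L) {
  n_dims <- as.integer(n_dims)
  n_groups <- as.integer(n_groups)
  n_per_group <- as.integer(n_per_group)
  if (n_dims < 2L) stop_config("n_dims must be >= 2")
  if (n_groups < 1L || n_per_group < 1L || n_reps < 1L)
    stop_config("n_groups, n_per_group and n_reps must be positive")
  if (between_var < 0) stop_config("between_var must be non-negative")
  in_grid <- n_dims >= 3 && n_dims <= 7 && n_groups >= 4 && n_groups <= 10 &&
    n_per_group >= 10 && n_per_group <= 50 && between_var <= 2
  if (!in_grid)
    warning("scenario lies outside the evaluated design grid ",
            "(J 3-7, K 4-10, n 10-50, between_var 0-2); proceeding", call. = FALSE)
  within_cov <- within_cov %||% exchangeable_cov(n_dims)
  within_cov <- as.matrix(within_cov)
  if (!all(dim(within_cov) == n_dims))
    stop_config("within_cov must be %d x %d", n_dims, n_dims)
  ev <- eigen((within_cov + t(within_cov)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  if (min(ev) <= 0) stop_config("within_cov must be positive definite")
  group_scale <- group_scale %||% rep(1, n_groups)
  if (length(group_scale) != n_groups || any(group_scale <= 0))
    stop_config("group_scale must be %d positive values", n_groups)
  structure(list(n_dims = n_dims, n_groups = n_groups,
                 n_per_group = n_per_group, between_var = between_var,
                 within_cov = within_cov, group_scale = group_scale,
                 n_reps = as.integer(n_reps), seed = as.integer(seed)),
            class = "sim_scenario")
}

#' Generate one replicate dataset from a simulation scenario
#'
#' Group means mu_(j,k) are drawn i.i.d. N(0, between_var) per variable
#' and group (independent across variables, matching the model's
#' univariate random-intercept prior); observations are drawn
#' MN(mu_k, s_k * Sigma_true) with s_k the group's variance multiplier.
#' Deterministic given (scenario seed, rep_index).
#'
#' @param scenario a `sim_scenario`.
#' @param rep_index replicate number (1-based).
#' @return A [grouped_observations()] object with groups "g1".."gK".
#' @export
simulate_grouped_dataset <- function(scenario, rep_index = 1L) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(scenario$seed + as.integer(rep_index))
  J <- scenario$n_dims
  K <- scenario$n_groups
  n <- scenario$n_per_group
  mu <- matrix(rnorm(K * J, 0, sqrt(scenario$between_var)), K, J)
  vals <- matrix(NA_real_, K * n, J)
  for (k in seq_len(K)) {
    rows <- (k - 1) * n + seq_len(n)
    vals[rows, ] <- MASS::mvrnorm(n, mu[k, ],
                                  scenario$group_scale[k] * scenario$within_cov)
  }
  grouped_observations(vals, rep(paste0("g", seq_len(K)), each = n),
                       paste0("V", seq_len(J)))
}

#' True hypervolume size of a scenario
#'
#' The volume of the level-0.95 ellipsoid of the known generating
#' within-group covariance -- the target both estimators are judged
#' against.
#'
#' @param scenario a `sim_scenario`.
#' @param level confidence level.
#' @return The true ellipsoid volume.
#' @export
true_volume <- function(scenario, level = 0.95) {
  stopifnot(inherits(scenario, "sim_scenario"))
  ellipsoid_volume(hypervolume(rep(0, scenario$n_dims),
                               scenario$within_cov, level))$volume
}

#' Relative volume error
#'
#' @param estimated estimated volume.
#' @param truth true volume (> 0).
#' @return (estimated - truth) / truth.
#' @export
relative_volume_error <- function(estimated, truth) {
  if (any(truth <= 0)) stop_config("true volume must be positive")
  (estimated - truth) / truth
}

#' Simulation-study MCMC defaults
#'
#' Reduced chains used inside the replicated simulation study: 10,000
#' iterations, 5,000 burn-in, 2 chains, thinning 5 (1,000 retained draws
#' per chain). The conjugate sampler mixes rapidly, so these short
#' chains estimate posterior-mean volumes to well within the replicate-
#' to-replicate spread.
#'
#' @param seed integer seed.
#' @return A [fit_config()].
#' @export
sim_fit_config <- function(seed = 1L) {
  fit_config(n_iterations = 10000L, n_burnin = 5000L, n_chains = 2L,
             thin = 5L, seed = seed)
}

#' Run all replicates of one simulation cell
#'
#' For each replicate: generate data, centre it, fit the structured
#' (model-based) and empirical models, estimate each volume as the
#' posterior mean of per-draw ellipsoid volumes, and record relative
#' errors against the scenario's true volume plus a convergence flag
#' (all R-hat < 1.1). Replicate-level fit failures are recorded, not
#' fatal; the cell fails only if more than 20% of replicates fail.
#'
#' @param scenario a `sim_scenario`.
#' @param config MCMC settings; default [sim_fit_config()]. Each
#'   replicate's fit seed is derived from the scenario seed.
#' @param level confidence level of the volume.
#' @return A `scenario_result` list: `rel_error_model`,
#'   `rel_error_empirical`, `converged_model`, `converged_empirical`
#'   (per-rep), `true_volume`, `rep_seeds`, `n_failed`.
#' @export
run_scenario <- function(scenario, config = sim_fit_config(), level = 0.95) {
  stopifnot(inherits(scenario, "sim_scenario"))
  R <- scenario$n_reps
  tv <- true_volume(scenario, level)
  err_m <- err_e <- rep(NA_real_, R)
  conv_m <- conv_e <- rep(NA, R)
  rep_seeds <- scenario$seed + seq_len(R)
  n_failed <- 0L
  for (r in seq_len(R)) {
    res <- tryCatch({
      dat <- simulate_grouped_dataset(scenario, r)
      dat <- center_observations(dat)$data
      cfg <- config
      # distinct, reproducible fit seed per replicate and model
      cfg$seed <- (scenario$seed + 7919L * r) %% 2147483639L
      fit_m <- fit_structured(dat, cfg)
      cfg$seed <- cfg$seed + 1L
      fit_e <- fit_empirical(dat, cfg)
      list(
        em = relative_volume_error(mean(volume_draws(fit_m, level)), tv),
        ee = relative_volume_error(mean(volume_draws(fit_e, level)), tv),
        cm = check_convergence(fit_m)$converged,
        ce = check_convergence(fit_e)$converged
      )
    }, error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
    } else {
      err_m[r] <- res$em; err_e[r] <- res$ee
      conv_m[r] <- res$cm; conv_e[r] <- res$ce
    }
  }
  if (n_failed > 0.2 * R)
    stop_mbhv("mbhv_numeric_error",
              "%d of %d replicates failed; scenario abandoned", n_failed, R)
  structure(list(rel_error_model = err_m, rel_error_empirical = err_e,
                 converged_model = conv_m, converged_empirical = conv_e,
                 true_volume = tv, rep_seeds = rep_seeds,
                 n_failed = n_failed, scenario = scenario),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf(
    "scenario J=%d K=%d n=%d sigma2_b=%g: median rel. error model %.3f, empirical %.3f (%d reps, %d failed)\n",
    x$scenario$n_dims, x$scenario$n_groups, x$scenario$n_per_group,
    x$scenario$between_var,
    stats::median(x$rel_error_model, na.rm = TRUE),
    stats::median(x$rel_error_empirical, na.rm = TRUE),
    x$scenario$n_reps, x$n_failed))
  invisible(x)
}

scenario_id <- function(scenario) {
  sprintf("J%d_K%d_n%d_b%g_s%d", scenario$n_dims, scenario$n_groups,
          scenario$n_per_group, scenario$between_var, scenario$seed)
}

scenario_rows <- function(res) {
  sc <- res$scenario
  R <- sc$n_reps
  base <- data.frame(
    scenario = scenario_id(sc), n_dims = sc$n_dims, n_groups = sc$n_groups,
    n_per_group = sc$n_per_group, between_var = sc$between_var,
    rep = rep(seq_len(R), 2),
    method = rep(c("model", "empirical"), each = R),
    rel_error = c(res$rel_error_model, res$rel_error_empirical),
    converged = c(res$converged_model, res$converged_empirical),
    stringsAsFactors = FALSE)
  base
}

#' Run a grid of simulation scenarios into a tidy table
#'
#' Results accumulate one row per replicate and method. When `out_csv`
#' is given, completed cells are appended incrementally and a re-run
#' skips any cell whose rows are already present, so interrupted grids
#' resume without duplicating work.
#'
#' @param scenarios list of `sim_scenario` objects.
#' @param config MCMC settings shared by all cells.
#' @param out_csv optional path to an incremental results CSV.
#' @param level confidence level of the volume.
#' @return Data frame with columns scenario, n_dims, n_groups,
#'   n_per_group, between_var, rep, method, rel_error, converged.
#' @export
run_grid <- function(scenarios, config = sim_fit_config(), out_csv = NULL,
                     level = 0.95) {
  if (length(scenarios) == 0L) stop_config("empty scenario list")
  done <- character(0)
  existing <- NULL
  if (!is.null(out_csv) && file.exists(out_csv)) {
    existing <- read.csv(out_csv, stringsAsFactors = FALSE)
    done <- unique(existing$scenario)
  }
  out <- if (is.null(existing)) list() else list(existing)
  for (sc in scenarios) {
    stopifnot(inherits(sc, "sim_scenario"))
    id <- scenario_id(sc)
    if (id %in% done) next
    rows <- scenario_rows(run_scenario(sc, config, level))
    out[[length(out) + 1]] <- rows
    if (!is.null(out_csv))
      write.table(rows, out_csv, sep = ",", row.names = FALSE,
                  col.names = !file.exists(out_csv), append = file.exists(out_csv))
  }
  do.call(rbind, out)
}
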