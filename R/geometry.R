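#' Define a hypervolume as a multivariate-normal confidence ellipsoid
#'
#' A hypervolume is the `level`-probability ellipsoid of a multivariate
#' normal with centre `center` and covariance `covariance`:
#' \{ y : (y - mu)' Sigma^-1 (y - mu) <= chi^2_J(level) \}.
#'
#' @param center numeric vector of length J.
#' @param covariance J x J symmetric positive-definite matrix.
#' @param level confidence level in (0, 1); default 0.95.
#' @return A `hypervolume` object.
#' @examples
#' hv <- hypervolume(c(0, 0), diag(2))
#' ellipsoid_volume(hv)$volume
#' @export
hypervolume <- function(center, covariance, level = 0.95) {
  center <- as.numeric(center)
  covariance <- as.matrix(covariance)
  j <- length(center)
  if (!all(dim(covariance) == j))
    stop_geometry("covariance must be %d x %d", j, j)
  if (!isTRUE(all.equal(covariance, t(covariance), tolerance = 1e-8)))
    stop_geometry("covariance must be symmetric")
  covariance <- (covariance + t(covariance)) / 2
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop_geometry("covariance must be positive definite (min eigenvalue %.3g)",
                  min(ev))
  if (level <= 0 || level >= 1)
    stop_geometry("level must lie strictly between 0 and 1")
  structure(list(center = center, covariance = covariance, level = level),
            class = "hypervolume")
}

#' @export
print.hypervolume <- function(x, ...) {
  cat(sprintf("hypervolume: J = %d, level = %g, volume = %g\n",
              length(x$center), x$level, ellipsoid_volume(x)$volume))
  invisible(x)
}

#' Extract the posterior-mean hypervolume from a fitted ensemble
#'
#' Uses the posterior-mean covariance and the pooled posterior-mean
#' centre (group means averaged per draw, then over draws).
#'
#' @param ensemble an `hv_ensemble`.
#' @param level confidence level.
#' @return A `hypervolume`.
#' @export
as_hypervolume <- function(ensemble, level = 0.95) {
  stopifnot(inherits(ensemble, "hv_ensemble"))
  s <- posterior_summary(ensemble)
  hypervolume(attr(s, "mean_mu"), attr(s, "mean_sigma"), level)
}

unit_ball_volume <- function(j) pi^(j / 2) / gamma(j / 2 + 1)

#' Semi-axes and volume of the confidence ellipsoid
#'
#' With eigenvalues lambda_1..lambda_J of Sigma and c the `level`
#' quantile of chi^2_J, the i-th semi-axis is sqrt(lambda_i * c) and the
#' volume is U_J * prod(semi-axes) with U_J the unit-ball volume
#' pi^(J/2) / Gamma(J/2 + 1); equivalently U_J * c^(J/2) * sqrt(det Sigma).
#'
#' @param hv a `hypervolume`.
#' @return List with `semi_axes` (decreasing) and `volume`.
#' @export
ellipsoid_volume <- function(hv) {
  stopifnot(inherits(hv, "hypervolume"))
  j <- length(hv$center)
  lambda <- eigen(hv$covariance, symmetric = TRUE, only.values = TRUE)$values
  cq <- qchisq(hv$level, df = j)
  semi <- sqrt(lambda * cq)
  list(semi_axes = semi, volume = unit_ball_volume(j) * prod(semi))
}

#' Squared Mahalanobis distance of a point from a hypervolume centre
#'
#' @param hv a `hypervolume`.
#' @param point numeric vector of length J, or a matrix with J columns.
#' @return Numeric vector of squared distances (y - mu)' Sigma^-1 (y - mu).
#' @export
mahalanobis_sq <- function(hv, point) {
  stopifnot(inherits(hv, "hypervolume"))
  m <- if (is.null(dim(point))) matrix(point, nrow = 1) else as.matrix(point)
  if (ncol(m) != length(hv$center))
    stop_geometry("point has %d coordinates but the hypervolume has %d dimensions",
                  ncol(m), length(hv$center))
  stats::mahalanobis(m, hv$center, hv$covariance)
}

# multivariate normal log-density via Cholesky
dmvnorm_log <- function(x, mu, sigma) {
  m <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  ch <- chol(sigma)
  logdet <- 2 * sum(log(diag(ch)))
  d2 <- stats::mahalanobis(m, mu, sigma)
  -0.5 * (ncol(m) * log(2 * pi) + logdet + d2)
}

#' Analytic probability of inclusion
#'
#' For a multivariate normal, ordering points by density is the same as
#' ordering by Mahalanobis distance, so the fraction of the distribution
#' with lower density than the tested point is the chi-square survival
#' function of its squared distance: p = 1 - F_chi2_J(d^2). This is the
#' closed-form limit of [inclusion_probability_mc()].
#'
#' @param hv a `hypervolume`.
#' @param point numeric vector (or matrix of points, one per row).
#' @return Inclusion probability(ies) in \[0, 1\].
#' @export
inclusion_probability_analytic <- function(hv, point) {
  stopifnot(inherits(hv, "hypervolume"))
  1 - pchisq(mahalanobis_sq(hv, point), df = length(hv$center))
}

#' Monte-Carlo probability of inclusion
#'
#' Draws `n_sim` observations from the fitted multivariate normal,
#' computes their densities, and returns the fraction with density less
#' than or equal to the tested point's density `q` (ties count as more
#' extreme). The point is declared inside the hypervolume when
#' p >= 1 - level.
#'
#' @param hv a `hypervolume`.
#' @param point numeric vector of length J.
#' @param n_sim number of simulated observations (>= 1000).
#' @param seed optional integer seed.
#' @return List of class `inclusion_result`: `q` (density of the point),
#'   `p`, `decision` ("inside"/"outside"), `n_sim`, and the Monte-Carlo
#'   standard error `mc_se`.
#' @export
inclusion_probability_mc <- function(hv, point, n_sim = 10000L, seed = NULL) {
  stopifnot(inherits(hv, "hypervolume"))
  if (n_sim < 1000L) stop_config("n_sim must be at least 1000")
  if (!is.null(seed)) set.seed(seed)
  logq <- dmvnorm_log(point, hv$center, hv$covariance)
  sims <- MASS::mvrnorm(n_sim, hv$center, hv$covariance)
  logd <- dmvnorm_log(sims, hv$center, hv$covariance)
  p <- mean(logd <= logq)
  structure(list(q = exp(logq), p = p,
                 decision = if (p >= 1 - hv$level) "inside" else "outside",
                 threshold = 1 - hv$level, n_sim = as.integer(n_sim),
                 mc_se = sqrt(p * (1 - p) / n_sim)),
            class = "inclusion_result")
}

#' @export
print.inclusion_result <- function(x, ...) {
  cat(sprintf("inclusion: p = %.4f (q = %.4g, threshold %.3g) -> %s\n",
              x$p, x$q, x$threshold, x$decision))
  invisible(x)
}

#' Posterior probability of inclusion
#'
#' Propagates posterior uncertainty by computing the probability of
#' inclusion under every retained draw (mu pooled over groups for
#' structured fits) and summarising. By default the analytic chi-square
#' form is used per draw; `method = "mc"` nests a Monte-Carlo test per
#' draw (much slower).
#'
#' @param ensemble an `hv_ensemble`.
#' @param point numeric vector of length J (same centering as the data
#'   the model was fitted to).
#' @param level confidence level defining the inside/outside decision.
#' @param summary `"mean"` or `"median"` of the per-draw p values.
#' @param method `"analytic"` (default) or `"mc"`.
#' @param n_sim simulated observations per draw for `method = "mc"`.
#' @param seed optional integer seed (used by `method = "mc"`).
#' @return List of class `inclusion_result` with `p` (the summary),
#'   `p_per_draw`, `q` (density at the posterior-mean parameters) and
#'   `decision` at threshold `1 - level`.
#' @export
inclusion_probability_posterior <- function(ensemble, point, level = 0.95,
                                            summary = c("mean", "median"),
                                            method = c("analytic", "mc"),
                                            n_sim = 10000L, seed = NULL) {
  stopifnot(inherits(ensemble, "hv_ensemble"))
  summary <- match.arg(summary)
  method <- match.arg(method)
  mus <- pooled_mean(ensemble)
  sgs <- sigma_draws(ensemble)
  n <- nrow(mus)
  if (n == 0L) stop_config("empty ensemble")
  if (length(point) != ncol(mus))
    stop_geometry("point has %d coordinates but the fit has %d variables",
                  length(point), ncol(mus))
  if (!is.null(seed)) set.seed(seed)
  p_draw <- vapply(seq_len(n), function(i) {
    hv_i <- hypervolume(mus[i, ], sgs[, , i], level)
    if (method == "analytic") inclusion_probability_analytic(hv_i, point)
    else inclusion_probability_mc(hv_i, point, n_sim)$p
  }, numeric(1))
  p <- if (summary == "mean") mean(p_draw) else stats::median(p_draw)
  hv_bar <- as_hypervolume(ensemble, level)
  structure(list(q = exp(dmvnorm_log(point, hv_bar$center, hv_bar$covariance)),
                 p = p, p_per_draw = p_draw,
                 decision = if (p >= 1 - level) "inside" else "outside",
                 threshold = 1 - level, summary = summary, n_sim = NULL,
                 mc_se = sd(p_draw) / sqrt(n)),
            class = "inclusion_result")
}

#' Sample points from a hypervolume
#'
#' Draws from the underlying multivariate normal, by default truncated
#' to the `level` ellipsoid by rejection (the hypervolume *is* the
#' ellipsoid, so identical hypervolumes overlap at exactly 1). The
#' expected acceptance rate of the rejection step equals `level`.
#'
#' @param hv a `hypervolume`.
#' @param n_points number of points to return.
#' @param seed optional integer seed.
#' @param truncate reject draws outside the ellipsoid (default TRUE).
#' @return An `n_points` x J matrix; attribute `acceptance_rate` records
#'   the fraction of raw proposals accepted.
#' @export
sample_hypervolume <- function(hv, n_points, seed = NULL, truncate = TRUE) {
  stopifnot(inherits(hv, "hypervolume"))
  if (n_points < 1L) stop_config("n_points must be positive")
  if (!is.null(seed)) set.seed(seed)
  j <- length(hv$center)
  if (!truncate) {
    out <- MASS::mvrnorm(n_points, hv$center, hv$covariance)
    attr(out, "acceptance_rate") <- 1
    return(matrix(out, ncol = j))
  }
  cq <- qchisq(hv$level, df = j)
  kept <- matrix(NA_real_, 0, j)
  proposed <- 0L
  while (nrow(kept) < n_points) {
    batch <- max(1000L, ceiling((n_points - nrow(kept)) / hv$level * 1.1))
    pts <- matrix(MASS::mvrnorm(batch, hv$center, hv$covariance), ncol = j)
    proposed <- proposed + batch
    ok <- mahalanobis_sq(hv, pts) <= cq
    kept <- rbind(kept, pts[ok, , drop = FALSE])
  }
  acc <- nrow(kept) / proposed
  kept <- kept[seq_len(n_points), , drop = FALSE]
  attr(kept, "acceptance_rate") <- acc
  kept
}

#' Monte-Carlo overlap between two hypervolumes
#'
#' Simulates `n_points` from each hypervolume (truncated to its
#' ellipsoid) and tests membership of each point in the *other*
#' hypervolume analytically via the Mahalanobis ellipsoid test. The
#' overlap is the number of shared points divided by the total number of
#' points simulated; the two directional containments are also reported.
#' Both hypervolumes are sampled from the same seed, which makes
#' `hv_overlap(a, b, ...)` and `hv_overlap(b, a, ...)` exactly symmetric.
#'
#' @param hv_a,hv_b `hypervolume` objects of the same dimension.
#' @param n_points points simulated from each hypervolume (>= 10000
#'   recommended; the Monte-Carlo standard error is reported).
#' @param seed optional integer seed.
#' @param truncate sample from the level-truncated distribution (default);
#'   `FALSE` uses the untruncated normal, which caps self-overlap near
#'   the confidence level.
#' @return List of class `overlap_result`: `overlap`,
#'   `containment_a_in_b`, `containment_b_in_a`, `n_points`, `mc_se`.
#' @export
hv_overlap <- function(hv_a, hv_b, n_points = 50000L, seed = NULL,
                       truncate = TRUE) {
  stopifnot(inherits(hv_a, "hypervolume"), inherits(hv_b, "hypervolume"))
  j <- length(hv_a$center)
  if (length(hv_b$center) != j)
    stop_geometry("dimension mismatch: %d vs %d", j, length(hv_b$center))
  pts_a <- sample_hypervolume(hv_a, n_points, seed = seed, truncate = truncate)
  pts_b <- sample_hypervolume(hv_b, n_points, seed = seed, truncate = truncate)
  cq_a <- qchisq(hv_a$level, df = j)
  cq_b <- qchisq(hv_b$level, df = j)
  a_in_b <- sum(mahalanobis_sq(hv_b, pts_a) <= cq_b)
  b_in_a <- sum(mahalanobis_sq(hv_a, pts_b) <= cq_a)
  ov <- (a_in_b + b_in_a) / (2 * n_points)
  structure(list(overlap = ov,
                 containment_a_in_b = a_in_b / n_points,
                 containment_b_in_a = b_in_a / n_points,
                 n_points = as.integer(n_points),
                 mc_se = sqrt(ov * (1 - ov) / (2 * n_points))),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "overlap = %.4f (A in B: %.4f, B in A: %.4f; n = %d per volume, mc_se = %.2g)\n",
    x$overlap, x$containment_a_in_b, x$containment_b_in_a, x$n_points, x$mc_se))
  invisible(x)
}

#' Per-draw ellipsoid volumes of a fitted ensemble
#'
#' The volume functional is nonlinear in Sigma, so the package's point
#' estimate of a fitted hypervolume's size is the posterior mean of the
#' per-draw volumes rather than the volume of the posterior-mean Sigma
#' (both are available; see [as_hypervolume()]).
#'
#' @param ensemble an `hv_ensemble`.
#' @param level confidence level.
#' @return Numeric vector of volumes, one per retained draw.
#' @export
volume_draws <- function(ensemble, level = 0.95) {
  stopifnot(inherits(ensemble, "hv_ensemble"))
  sgs <- sigma_draws(ensemble)
  j <- dim(sgs)[1]
  cq <- qchisq(level, df = j)
  u <- unit_ball_volume(j)
  apply(sgs, 3, function(s) u * cq^(j / 2) * sqrt(max(det(s), 0)))
}
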