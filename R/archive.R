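#' Write a fitted ensemble to a JSON archive
#'
#' Stores the model kind, MCMC configuration, prior, centering
#' transform, labels and all chain draws at full numeric precision, so
#' an archive fully reproduces downstream geometry computations.
#'
#' @param ensemble an `hv_ensemble`.
#' @param path output path (conventionally `ensemble.json`).
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "hv_ensemble"))
  payload <- list(
    format = "mbhv-ensemble-1",
    model_kind = ensemble$model_kind,
    config = unclass(ensemble$config),
    prior = ensemble$prior,
    variable_names = ensemble$variable_names,
    group_names = ensemble$group_names,
    centering = if (is.null(ensemble$centering)) NULL else
      unclass(ensemble$centering),
    chains = lapply(ensemble$chains, function(ch)
      list(mu = ch$mu, sigma = ch$sigma))
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a fitted ensemble from a JSON archive
#'
#' @param path path written by [write_ensemble()].
#' @return An `hv_ensemble`.
#' @export
read_ensemble <- function(path) {
  if (!file.exists(path)) stop_config("archive not found: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(raw$format, "mbhv-ensemble-1"))
    stop_data("'%s' is not an mbhv ensemble archive", path)
  cfg <- do.call(fit_config, raw$config[c("n_iterations", "n_burnin",
                                          "n_chains", "thin", "epsilon", "seed")])
  chains <- if (is.data.frame(raw$chains)) {
    # jsonlite simplifies a list of homogeneous records to a data frame
    lapply(seq_len(nrow(raw$chains)), function(i)
      list(mu = raw$chains$mu[i][[1]], sigma = raw$chains$sigma[i][[1]]))
  } else {
    lapply(raw$chains, function(ch) list(mu = ch$mu, sigma = ch$sigma))
  }
  centering <- if (is.null(raw$centering)) NULL else
    structure(list(offsets = raw$centering$offsets,
                   scales = raw$centering$scales),
              class = "centering_transform")
  structure(list(model_kind = raw$model_kind, config = cfg, chains = chains,
                 prior = list(nu0 = raw$prior$nu0,
                              rate = as.matrix(raw$prior$rate)),
                 variable_names = raw$variable_names,
                 group_names = raw$group_names,
                 centering = centering),
            class = "hv_ensemble")
}
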