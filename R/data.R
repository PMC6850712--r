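#' Grouped multivariate observations
#'
#' Container for an N x J matrix of numeric ecological variables together
#' with a group label per row (e.g. vegetation plots nested in survey
#' squares). Group labels are encoded as integers 1..K in order of first
#' appearance; the hierarchical model treats rows sharing a label as
#' exchangeable draws around that group's mean vector.
#'
#' @param values numeric matrix (or data frame coercible to one), one row
#'   per observation, one column per variable.
#' @param groups vector of group identifiers, one per row.
#' @param variable_names optional character vector of column labels;
#'   defaults to the column names of `values`.
#' @return An object of class `grouped_obs` with elements `values`
#'   (matrix with column names), `groups` (integer codes 1..K),
#'   `variable_names`, and `group_names` (original labels, first-appearance
#'   order).
#' @examples
#' y <- matrix(rnorm(24), 12, 2)
#' d <- grouped_observations(y, rep(c("a", "b"), each = 6))
#' d$group_names
#' @export
grouped_observations <- function(values, groups, variable_names = NULL) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values))
    stop_data("'values' must be a numeric matrix")
  n <- nrow(values)
  j <- ncol(values)
  if (length(groups) != n)
    stop_data("length of 'groups' (%d) must equal nrow(values) (%d)",
              length(groups), n)
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_data("non-finite value at row %d, column %d", bad[1, 1], bad[1, 2])
  if (n < j + 2)
    stop_data("need at least J + 2 = %d observations to estimate a %dx%d covariance (got %d)",
              j + 2, j, j, n)
  if (j < 1) stop_data("at least one variable column is required")
  if (j == 1)
    warning("only one variable: a hypervolume needs >= 2 dimensions; ",
            "proceeding with a 1-d interval", call. = FALSE)
  variable_names <- variable_names %||% colnames(values) %||% paste0("V", seq_len(j))
  if (length(variable_names) != j)
    stop_config("variable_names must have length %d", j)
  colnames(values) <- variable_names
  group_names <- as.character(unique(groups))
  codes <- match(as.character(groups), group_names)
  structure(
    list(values = values, groups = codes,
         variable_names = variable_names, group_names = group_names),
    class = "grouped_obs"
  )
}

#' @export
print.grouped_obs <- function(x, ...) {
  cat(sprintf("Grouped observations: N = %d, J = %d, K = %d\n",
              nrow(x$values), ncol(x$values), length(x$group_names)))
  cat("variables:", paste(x$variable_names, collapse = ", "), "\n")
  cat("group sizes:", paste(tabulate(x$groups), collapse = ", "), "\n")
  invisible(x)
}

n_groups <- function(data) length(data$group_names)

#' Read grouped observations from a CSV file
#'
#' Expects an RFC-4180 CSV with a header row, '.' decimal separator,
#' numeric variable columns and one group-label column. Missing or
#' non-numeric cells are rejected (the model has no missingness
#' mechanism), with the offending row and column named.
#'
#' @param path path to the CSV file.
#' @param variable_columns character vector of variable column names.
#' @param group_column name of the group-label column.
#' @return A [grouped_observations()] object.
#' @export
load_grouped_csv <- function(path, variable_columns, group_column) {
  if (!file.exists(path)) stop_config("file not found: %s", path)
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
                 error = function(e) stop_data("cannot parse CSV '%s': %s",
                                               path, conditionMessage(e)))
  if (nrow(df) == 0) stop_data("CSV '%s' contains no data rows", path)
  missing_cols <- setdiff(c(variable_columns, group_column), names(df))
  if (length(missing_cols) > 0)
    stop_config("column(s) not present in '%s': %s", path,
                paste(missing_cols, collapse = ", "))
  vals <- matrix(NA_real_, nrow(df), length(variable_columns),
                 dimnames = list(NULL, variable_columns))
  for (col in variable_columns) {
    raw <- df[[col]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) | (!is.na(raw) & trimws(as.character(raw)) == ""))
    if (length(bad) > 0)
      stop_data("missing or non-numeric value in column '%s', row %d",
                col, bad[1])
    vals[, col] <- num
  }
  grouped_observations(vals, df[[group_column]], variable_columns)
}

#' Write grouped observations to CSV
#'
#' Numeric values are written with 17 significant digits so that a
#' write/read cycle reproduces the doubles (and the text) exactly.
#'
#' @param data a `grouped_obs` object.
#' @param path output path.
#' @param group_column name for the group-label column.
#' @return `path`, invisibly.
#' @export
write_grouped_csv <- function(data, path, group_column = "group") {
  stopifnot(inherits(data, "grouped_obs"))
  txt <- apply(data$values, 2, function(x) sprintf("%.17g", x))
  if (is.null(dim(txt))) txt <- matrix(txt, nrow = 1)
  df <- as.data.frame(txt, stringsAsFactors = FALSE)
  names(df) <- data$variable_names
  df[[group_column]] <- data$group_names[data$groups]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Center grouped observations on their grand means
#'
#' Subtracts the per-variable grand mean (not per-group means: group
#' shifts belong to the model's random intercepts). Centering improves
#' MCMC convergence and is assumed by the N(0, epsilon) prior on group
#' means. Variables are not rescaled by default; set `standardize = TRUE`
#' to also divide by the per-variable standard deviation.
#'
#' @param data a `grouped_obs` object.
#' @param standardize also scale each variable to unit standard deviation.
#' @return A list with `data` (the transformed `grouped_obs`) and
#'   `transform` (a `centering_transform` holding the offsets and scales).
#' @examples
#' d <- grouped_observations(matrix(1:12 + 0, 6, 2), rep(1:2, 3))
#' cd <- center_observations(d)
#' colMeans(cd$data$values)
#' @export
center_observations <- function(data, standardize = FALSE) {
  stopifnot(inherits(data, "grouped_obs"))
  offsets <- colMeans(data$values)
  scales <- if (standardize) apply(data$values, 2, sd) else rep(1, ncol(data$values))
  if (any(scales <= 0)) stop_degenerate("constant column cannot be standardized")
  tr <- structure(list(offsets = offsets, scales = scales),
                  class = "centering_transform")
  out <- data
  out$values <- sweep(sweep(data$values, 2, offsets), 2, scales, "/")
  list(data = out, transform = tr)
}

#' Apply a stored centering transform to new values
#'
#' Used to put new observations (e.g. points whose inclusion is to be
#' tested) on the same scale as the data a model was fitted to.
#'
#' @param transform a `centering_transform`.
#' @param values numeric matrix or vector with J columns/elements.
#' @return Transformed values, same shape as the input.
#' @export
apply_centering <- function(transform, values) {
  stopifnot(inherits(transform, "centering_transform"))
  vec <- is.null(dim(values))
  m <- if (vec) matrix(values, nrow = 1) else as.matrix(values)
  if (ncol(m) != length(transform$offsets))
    stop_config("expected %d variables, got %d", length(transform$offsets), ncol(m))
  out <- sweep(sweep(m, 2, transform$offsets), 2, transform$scales, "/")
  if (vec) drop(out) else out
}

#' Invert a centering transform
#'
#' @param transform a `centering_transform`.
#' @param values centered values (matrix or vector).
#' @return Values on the original scale.
#' @export
invert_centering <- function(transform, values) {
  stopifnot(inherits(transform, "centering_transform"))
  vec <- is.null(dim(values))
  m <- if (vec) matrix(values, nrow = 1) else as.matrix(values)
  out <- sweep(sweep(m, 2, transform$scales, "*"), 2, transform$offsets, "+")
  if (vec) drop(out) else out
}

#' Pooled sample covariance of the raw data
#'
#' The covariance of all observations pooled across groups (denominator
#' N - 1). This matrix serves as the Wishart prior rate matrix for the
#' precision, so a singular result (e.g. a constant or duplicated
#' column) is an error.
#'
#' @param data a `grouped_obs` object.
#' @return A J x J symmetric positive-definite matrix.
#' @export
raw_covariance <- function(data) {
  stopifnot(inherits(data, "grouped_obs"))
  s <- cov(data$values)
  ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= max(ev) * 1e-10 || min(ev) <= 0)
    stop_degenerate(
      "pooled covariance is singular or near-singular (min eigenvalue %.3g); it cannot serve as a Wishart prior scale",
      min(ev))
  s
}
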