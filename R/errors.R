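# Classed conditions so callers (and the CLI exit-code mapping) can
# distinguish configuration mistakes from data problems.

stop_mbhv <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "mbhv_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_config <- function(msg, ...) stop_mbhv("mbhv_config_error", msg, ...)
stop_data <- function(msg, ...) stop_mbhv("mbhv_data_error", msg, ...)
stop_degenerate <- function(msg, ...) stop_mbhv("mbhv_degenerate_error", msg, ...)
stop_geometry <- function(msg, ...) stop_mbhv("mbhv_geometry_error", msg, ...)
stop_diagnostic <- function(msg, ...) stop_mbhv("mbhv_diagnostic_error", msg, ...)

`%||%` <- function(a, b) if (is.null(a)) b else a
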