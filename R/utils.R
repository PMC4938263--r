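# Internal helpers: classed conditions and tiny numeric utilities.

stop_specbind <- function(class, fmt, ...) {
  msg <- if (length(list(...))) sprintf(fmt, ...) else fmt
  stop(errorCondition(msg, class = c(class, "specbind_error")))
}

stop_domain <- function(fmt, ...) stop_specbind("specbind_domain_error", fmt, ...)
stop_format <- function(fmt, ...) stop_specbind("specbind_format_error", fmt, ...)
stop_grid <- function(fmt, ...) stop_specbind("specbind_grid_error", fmt, ...)
stop_window <- function(fmt, ...) stop_specbind("specbind_window_error", fmt, ...)
stop_insufficient <- function(fmt, ...) {
  stop_specbind("specbind_insufficient_data_error", fmt, ...)
}
stop_config <- function(fmt, ...) stop_specbind("specbind_config_error", fmt, ...)

`%||%` <- function(x, y) if (is.null(x)) y else x

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_positive <- function(x, name) {
  if (!is_number(x) || x <= 0) {
    stop_domain("`%s` must be a single positive finite number", name)
  }
  invisible(x)
}

## R-squared of a fitted lm, guarded against a zero-variance response
## (a flat titration has no explainable variance; report NA, not NaN).
r_squared_of <- function(fit) {
  y <- fit$model[[1L]]
  sst <- sum((y - mean(y))^2)
  if (sst <= .Machine$double.eps * length(y)) return(NA_real_)
  max(0, min(1, 1 - sum(fit$residuals^2) / sst))
}
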