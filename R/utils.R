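# classed conditions used across the package
abort_domain <- function(msg, ...) {
  rlang::abort(msg, class = "afmvisc_domain_error", ...)
}

abort_data <- function(msg, ...) {
  rlang::abort(msg, class = "afmvisc_data_error", ...)
}

abort_fit <- function(msg, ...) {
  rlang::abort(msg, class = "afmvisc_fit_error", ...)
}

abort_format <- function(msg, ...) {
  rlang::abort(msg, class = c("afmvisc_format_error", "afmvisc_data_error"), ...)
}

abort_numeric <- function(msg, ...) {
  rlang::abort(msg, class = "afmvisc_numerical_error", ...)
}

abort_usage <- function(msg, ...) {
  rlang::abort(msg, class = "afmvisc_usage_error", ...)
}

check_time <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t))) {
    abort_domain("time `t` must be finite and numeric.")
  }
  if (any(t < 0)) {
    abort_domain("time `t` must be non-negative.")
  }
  invisible(t)
}

# polynomial product, coefficients in increasing order of the Laplace
# variable s (degree grows by convolution)
poly_mul <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i + seq_along(b) - 1L
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

poly_eval <- function(coefs, s) {
  out <- 0 * s
  for (i in rev(seq_along(coefs))) out <- out * s + coefs[i]
  out
}
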