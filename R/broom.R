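#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a force-curve fit
#'
#' @param x An `afm_fit` (from [fit_three_point()],
#'   [fit_least_squares()] or [fit_dmt_loading()]).
#' @param ... Unused, for generic consistency.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `units`.
#' @examples
#' sc <- tmv_scenario()
#' curve <- generate_relaxation_curve(sc$solid, sc$contact)
#' tidy(fit_three_point(curve, sc$contact, v1 = sc$v))
#' @exportS3Method generics::tidy
tidy.afm_fit <- function(x, ...) {
  units <- c(
    E1_GPa = "GPa", E2_GPa = "GPa", eta_GPa_ms = "GPa ms",
    E1s_GPa = "GPa", E_star_GPa = "GPa"
  )
  tibble::tibble(
    term = sub("_(GPa(_ms)?)$", "", names(x$estimates)),
    estimate = unlist(x$estimates, use.names = FALSE),
    units = unname(units[names(x$estimates)])
  )
}

#' Glance at a force-curve fit
#'
#' @inheritParams tidy.afm_fit
#' @return A one-row tibble: `r.squared`, `sigma` (residual RMSE),
#'   `nobs`, `method`, `n.warnings`.
#' @exportS3Method generics::glance
glance.afm_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    sigma = sqrt(mean(x$residuals^2)),
    nobs = length(x$residuals),
    method = x$method,
    n.warnings = length(x$warnings)
  )
}

#' Augment curve data with fitted values and residuals
#'
#' @inheritParams tidy.afm_fit
#' @return The fit's curve with `.fitted` and `.resid` columns
#'   appended (force for relaxation fits, displacement for loading
#'   fits).
#' @exportS3Method generics::augment
augment.afm_fit <- function(x, ...) {
  out <- tibble::as_tibble(x$curve)
  out$.fitted <- x$fitted
  out$.resid <- x$residuals
  out
}

#' Tidy the closed-form relaxation coefficients
#'
#' @param x A `"relaxation_coefficients"` object.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `units` for Ar, Br, Cr,
#'   alpha, beta and the geometric prefactor.
#' @exportS3Method generics::tidy
tidy.relaxation_coefficients <- function(x, ...) {
  tibble::tibble(
    term = c("Ar", "Br", "Cr", "alpha", "beta", "prefactor"),
    estimate = c(x$Ar, x$Br, x$Cr, x$alpha, x$beta, x$prefactor),
    units = c("GPa", "GPa", "GPa", "1/ms", "1/ms", "nm^2")
  )
}
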