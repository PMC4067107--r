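#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a force curve
#'
#' @param object An [afm_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.afm_curve <- function(object, ...) {
  kind <- curve_kind(object)
  xlab <- if (kind == "relaxation") "time (ms)" else "Z-piezo displacement (nm)"
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(x = .data[[if (kind == "relaxation") "time_ms" else "z_nm"]],
                 y = .data[["force_nN"]])
  ) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = xlab, y = "force (nN)",
                  title = sprintf("AFM %s curve", kind)) +
    ggplot2::theme_minimal()
}

#' Plot a fit over its data
#'
#' Shows the measured points and the fitted model curve (evaluated on
#' a dense grid for relaxation fits).
#'
#' @param object An `afm_fit`.
#' @param n_dense Number of dense model-evaluation points.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.afm_fit <- function(object, n_dense = 200, ...) {
  data <- tibble::as_tibble(object$curve)
  if (inherits(object, "afm_relaxation_fit")) {
    grid <- seq(min(data$time_ms), max(data$time_ms), length.out = n_dense)
    model <- tibble::tibble(
      time_ms = grid,
      force_nN = force_relaxation(object$solid, object$contact, grid)
    )
    p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$time_ms, y = .data$force_nN)) +
      ggplot2::geom_point(size = 1.2) +
      ggplot2::geom_line(data = model, colour = "firebrick") +
      ggplot2::labs(x = "time (ms)", y = "force (nN)")
  } else {
    grid <- seq(min(data$force_nN), max(data$force_nN), length.out = n_dense)
    model <- tibble::tibble(
      z_nm = loading_displacement(object$estimates$E1s_GPa, object$v_s,
                                  object$contact, grid),
      force_nN = grid
    )
    p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$z_nm, y = .data$force_nN)) +
      ggplot2::geom_point(size = 1.2) +
      ggplot2::geom_line(data = model, colour = "firebrick") +
      ggplot2::labs(x = "Z-piezo displacement (nm)", y = "force (nN)")
  }
  p +
    ggplot2::labs(title = sprintf("%s fit, R² = %.4f", object$method, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot the dynamic-modulus spectrum of a standard solid
#'
#' Storage and loss shear moduli over a log-spaced frequency band
#' (see [storage_loss_moduli()]).
#'
#' @param solid A [zener_parallel()] solid.
#' @param omega_range Two positive frequencies (rad/s) bounding the
#'   band.
#' @param n Number of frequency points.
#' @param include_equilibrium_storage Passed to
#'   [storage_loss_moduli()].
#' @return A ggplot.
#' @examples
#' plot_dynamic_moduli(zener_parallel(2.14, 0.0213, 12.4, v1 = 0.380829))
#' @export
plot_dynamic_moduli <- function(solid, omega_range = c(1e-2, 1e2), n = 200,
                                include_equilibrium_storage = FALSE) {
  stopifnot(length(omega_range) == 2, all(omega_range > 0))
  omega <- exp(seq(log(omega_range[1]), log(omega_range[2]), length.out = n))
  spec <- storage_loss_moduli(solid, omega, include_equilibrium_storage)
  long <- tibble::tibble(
    omega = rep(spec$omega, 2),
    modulus_MPa = c(spec$g_storage_MPa, spec$g_loss_MPa),
    component = rep(c("storage G'", "loss G''"), each = nrow(spec))
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$omega, y = .data$modulus_MPa,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "angular velocity (rad/s)", y = "shear modulus (MPa)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
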