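#' Uniaxial stress relaxation of the parallel standard solid
#'
#' Stress response to a step uniaxial strain `eps0` applied at t = 0:
#' \deqn{\sigma(t) = \epsilon_0 (E_1 + E_2 e^{-E_2 t/\eta}),}
#' relaxing from the instantaneous modulus `E1 + E2` to the
#' equilibrium modulus `E1`.
#'
#' @param solid A [zener_parallel()] solid.
#' @param eps0 Applied strain (dimensionless).
#' @param t Time (ms), non-negative; vectorized.
#' @return Stress (GPa).
#' @examples
#' s <- zener_parallel(E1 = 3, E2 = 0.0213, eta = 12.4, v1 = 0.38)
#' stress_relaxation(s, eps0 = 0.1, t = c(0, 500, 5000))
#' @export
stress_relaxation <- function(solid, eps0, t) {
  stopifnot(inherits(solid, "zener_parallel"))
  check_time(t)
  eps0 * (solid$E1 + solid$E2 * exp(-solid$E2 * t / solid$eta))
}

#' Uniaxial strain creep of the parallel standard solid
#'
#' Strain response to a step uniaxial stress `sigma0`:
#' \deqn{\epsilon(t) = \sigma_0 J(t), \quad
#'   J(t) = \frac{1}{E_1} + \Big(\frac{1}{E_1+E_2} - \frac{1}{E_1}\Big)
#'   e^{-E_1 E_2 t / (\eta (E_1+E_2))},}
#' the Zener creep compliance with instantaneous value `1/(E1+E2)` and
#' relaxed value `1/E1`.
#'
#' @inheritParams stress_relaxation
#' @param sigma0 Applied stress (GPa).
#' @return Strain (dimensionless).
#' @export
strain_creep <- function(solid, sigma0, t) {
  stopifnot(inherits(solid, "zener_parallel"))
  check_time(t)
  E1 <- solid$E1
  E2 <- solid$E2
  rate <- E1 * E2 / (solid$eta * (E1 + E2))
  J <- 1 / E1 + (1 / (E1 + E2) - 1 / E1) * exp(-rate * t)
  sigma0 * J
}

#' Shear stress relaxation modulus of the parallel standard solid
#'
#' \deqn{G(t) = G_1 + G_2 e^{-G_2 t/\eta},} the ratio of shear stress
#' to a constant applied shear strain.
#'
#' @inheritParams stress_relaxation
#' @return Shear relaxation modulus (GPa).
#' @export
relaxation_modulus <- function(solid, t) {
  stopifnot(inherits(solid, "zener_parallel"))
  check_time(t)
  solid$G1 + solid$G2 * exp(-solid$G2 * t / solid$eta)
}

#' Storage and loss shear moduli of the parallel standard solid
#'
#' Closed-form dynamic moduli obtained from the Fourier sine/cosine
#' transforms of the decaying part of the shear relaxation modulus:
#' \deqn{G'(\omega) = \frac{\omega^2 G_2 \eta^2}{G_2^2 + \omega^2\eta^2},
#'  \qquad
#'  G''(\omega) = \frac{G_2^2 \omega \eta}{G_2^2 + \omega^2 \eta^2},}
#' with `eta` converted internally from GPa ms to GPa s so that
#' `omega` is in rad/s. By default the equilibrium spring `G1`
#' contributes nothing to the storage modulus (only the decaying
#' Maxwell arm is transformed); set `include_equilibrium_storage =
#' TRUE` to add the constant `G1` to `G'`, the usual convention for a
#' solid with a finite equilibrium modulus. The loss modulus peaks at
#' `G2/2` at `omega = G2/eta`.
#'
#' @inheritParams stress_relaxation
#' @param omega Angular frequency (rad/s), non-negative; vectorized.
#' @param include_equilibrium_storage Add the constant `G1` term to
#'   the storage modulus? Default `FALSE`.
#' @return A tibble with columns `omega` (rad/s), `g_storage_MPa` and
#'   `g_loss_MPa`.
#' @examples
#' s <- zener_parallel(E1 = 2.14, E2 = 0.0213, eta = 12.4, v1 = 0.380829)
#' storage_loss_moduli(s, omega = c(0.1, 0.62, 10))
#' @export
storage_loss_moduli <- function(solid, omega, include_equilibrium_storage = FALSE) {
  stopifnot(inherits(solid, "zener_parallel"))
  if (any(!is.finite(omega)) || any(omega < 0)) {
    abort_domain("`omega` must be finite and non-negative.")
  }
  G1 <- solid$G1
  G2 <- solid$G2
  eta_s <- solid$eta * 1e-3 # GPa ms -> GPa s
  den <- G2^2 + omega^2 * eta_s^2
  gp <- omega^2 * G2 * eta_s^2 / den
  gpp <- G2^2 * omega * eta_s / den
  if (include_equilibrium_storage) gp <- gp + G1
  tibble::tibble(
    omega = omega,
    g_storage_MPa = gp * 1e3,
    g_loss_MPa = gpp * 1e3
  )
}

#' Dynamic moduli by direct numerical Fourier transform
#'
#' Independent numerical route to the storage and loss moduli: the
#' relaxation function is split into its long-time constant and a
#' decaying part `g(t)`, and
#' \deqn{G'(\omega) = \omega \int_0^\infty g(t) \sin(\omega t)\,dt,
#'  \qquad
#'  G''(\omega) = \omega \int_0^\infty g(t) \cos(\omega t)\,dt}
#' are evaluated by adaptive quadrature, truncating the integral where
#' the decaying part has fallen below `1e-12` of its initial value and
#' integrating piecewise over half-periods of the oscillating kernel.
#' Serves as an oracle for [storage_loss_moduli()].
#'
#' @param relaxation_fn Function of time in seconds returning the
#'   shear relaxation modulus in GPa; must decay to a constant.
#' @param omega Angular frequencies (rad/s), non-negative.
#' @param include_equilibrium_storage Add the long-time constant to
#'   the storage modulus? Default `FALSE`, matching
#'   [storage_loss_moduli()].
#' @return A tibble with columns `omega`, `g_storage_MPa`, `g_loss_MPa`.
#' @examples
#' s <- zener_parallel(E1 = 2.14, E2 = 0.0213, eta = 12.4, v1 = 0.380829)
#' fn <- function(t_s) relaxation_modulus(s, t_s * 1e3)
#' dynamic_moduli_numeric(fn, omega = 0.62)
#' @export
dynamic_moduli_numeric <- function(relaxation_fn, omega,
                                   include_equilibrium_storage = FALSE) {
  if (any(!is.finite(omega)) || any(omega < 0)) {
    abort_domain("`omega` must be finite and non-negative.")
  }
  t_far <- 1e9
  g_inf <- relaxation_fn(t_far)
  g <- function(t) relaxation_fn(t) - g_inf
  g0 <- g(0)
  if (abs(g0) < .Machine$double.eps) {
    return(tibble::tibble(
      omega = omega,
      g_storage_MPa = (if (include_equilibrium_storage) g_inf else 0) * 1e3 + 0 * omega,
      g_loss_MPa = 0 * omega
    ))
  }
  # truncation horizon: decaying part below 1e-12 of its initial value
  t_end <- 1
  while (abs(g(t_end)) > 1e-12 * abs(g0)) {
    t_end <- t_end * 2
    if (t_end > 1e8) {
      abort_numeric("relaxation function does not decay; cannot form the Fourier integrals.")
    }
  }
  while (t_end > 1e-6 && abs(g(t_end / 2)) <= 1e-12 * abs(g0)) t_end <- t_end / 2
  one_omega <- function(w) {
    if (w == 0) {
      return(c(0, 0))
    }
    breaks <- unique(c(seq(0, t_end, by = pi / w), t_end))
    sine <- sum(vapply(seq_len(length(breaks) - 1), function(i) {
      stats::integrate(function(t) g(t) * sin(w * t), breaks[i], breaks[i + 1],
                       rel.tol = 1e-10, abs.tol = 1e-14)$value
    }, numeric(1)))
    cosine <- sum(vapply(seq_len(length(breaks) - 1), function(i) {
      stats::integrate(function(t) g(t) * cos(w * t), breaks[i], breaks[i + 1],
                       rel.tol = 1e-10, abs.tol = 1e-14)$value
    }, numeric(1)))
    c(w * sine, w * cosine)
  }
  vals <- vapply(omega, one_omega, numeric(2))
  gp <- vals[1, ]
  if (include_equilibrium_storage) gp <- gp + g_inf
  tibble::tibble(
    omega = omega,
    g_storage_MPa = gp * 1e3,
    g_loss_MPa = vals[2, ] * 1e3
  )
}
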