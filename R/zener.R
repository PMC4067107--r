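#' Standard linear solid, series (spring + Kelvin-Voigt) topology
#'
#' Constructs a three-element standard solid (Zener) material in the
#' series topology: an instantaneous spring `E1` in series with a
#' Kelvin-Voigt element (spring `E2` in parallel with a dashpot `eta`).
#' This topology carries the instantaneous Young's modulus `E1` and the
#' relaxed series modulus `E1*E2/(E1+E2)`; its shear response relaxes
#' from `G1` at t = 0 to `G1*G2/(G1+G2)` at long times. The volumetric
#' response is assumed elastic, governed by the bulk modulus `K1` of
#' the instantaneous spring alone.
#'
#' @param E1 Young's modulus of the instantaneous spring (GPa).
#' @param E2 Young's modulus of the retarded spring (GPa).
#' @param eta Dashpot viscosity (GPa ms). `eta = 0` is allowed as the
#'   degenerate purely elastic limit.
#' @param v1,v2 Poisson ratios of the two springs (dimensionless, in
#'   (-1, 0.5); `v1 = 0.5` is rejected because the bulk modulus
#'   diverges). `v2` defaults to `v1`.
#'
#' @return An object of class `c("zener_series", "zener_solid")`: a
#'   list with the inputs plus derived shear moduli `G1`, `G2` (GPa)
#'   and bulk modulus `K1` (GPa).
#' @examples
#' zener_series(E1 = 0.032, E2 = 0.0213, eta = 12.4, v1 = 0.380829)
#' @export
zener_series <- function(E1, E2, eta, v1, v2 = v1) {
  check_zener_args(E1, E2, eta, v1, v2)
  out <- list(
    E1 = E1, E2 = E2, eta = eta, v1 = v1, v2 = v2,
    G1 = shear_modulus(E1, v1),
    G2 = shear_modulus(E2, v2),
    K1 = bulk_modulus(E1, v1)
  )
  structure(out, class = c("zener_series", "zener_solid"))
}

#' Standard linear solid, parallel (spring + Maxwell arm) topology
#'
#' Constructs the standard solid in the parallel topology: an
#' equilibrium spring `E1` in parallel with a Maxwell arm (spring `E2`
#' in series with a dashpot `eta`). The uniaxial relaxation modulus is
#' `E1 + E2*exp(-E2*t/eta)`: instantaneous modulus `E1 + E2`, relaxed
#' modulus `E1`.
#'
#' @inheritParams zener_series
#' @param E1 Young's modulus of the equilibrium (relaxed) spring (GPa).
#' @param E2 Young's modulus of the Maxwell-arm spring (GPa).
#'
#' @return An object of class `c("zener_parallel", "zener_solid")` with
#'   derived `G1`, `G2`, `K1` as for [zener_series()].
#' @examples
#' zener_parallel(E1 = 2.14, E2 = 0.0213, eta = 12.4, v1 = 0.380829)
#' @export
zener_parallel <- function(E1, E2, eta, v1, v2 = v1) {
  check_zener_args(E1, E2, eta, v1, v2)
  out <- list(
    E1 = E1, E2 = E2, eta = eta, v1 = v1, v2 = v2,
    G1 = shear_modulus(E1, v1),
    G2 = shear_modulus(E2, v2),
    K1 = bulk_modulus(E1, v1)
  )
  structure(out, class = c("zener_parallel", "zener_solid"))
}

shear_modulus <- function(E, v) E / (2 * (1 + v))
bulk_modulus <- function(E, v) E / (3 * (1 - 2 * v))

check_zener_args <- function(E1, E2, eta, v1, v2) {
  for (nm in c("E1", "E2", "eta", "v1", "v2")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      abort_domain(sprintf("`%s` must be a single finite number.", nm))
    }
  }
  if (E1 <= 0 || E2 <= 0) {
    abort_domain("Young's moduli `E1` and `E2` must be positive.")
  }
  if (eta < 0) {
    abort_domain("viscosity `eta` must be non-negative.")
  }
  for (nm in c("v1", "v2")) {
    v <- get(nm)
    if (v <= -1 || v >= 0.5) {
      abort_domain(sprintf(
        "Poisson ratio `%s` must lie in (-1, 0.5); %g is outside (0.5 makes the bulk modulus diverge).",
        nm, v
      ))
    }
  }
  invisible(TRUE)
}

#' @export
print.zener_solid <- function(x, ...) {
  topo <- if (inherits(x, "zener_series")) {
    "series (spring + Kelvin-Voigt)"
  } else {
    "parallel (spring + Maxwell arm)"
  }
  cat("<standard linear solid, ", topo, ">\n", sep = "")
  cat(sprintf("  E1  = %g GPa (v1 = %g)\n", x$E1, x$v1))
  cat(sprintf("  E2  = %g GPa (v2 = %g)\n", x$E2, x$v2))
  cat(sprintf("  eta = %g GPa ms\n", x$eta))
  cat(sprintf("  derived: G1 = %g, G2 = %g, K1 = %g GPa\n", x$G1, x$G2, x$K1))
  invisible(x)
}

#' Convert between the two standard-solid topologies
#'
#' The series and parallel Zener topologies describe the same family of
#' shear relaxation functions; these converters map one
#' parameterization onto the other so that the shear relaxation modulus
#' is identical: matching instantaneous modulus, relaxed modulus and
#' relaxation rate. Poisson ratios are carried through unchanged
#' (`v1`, `v2` label the equilibrium-like and retarded-like springs in
#' either topology), and the Young's moduli of the target topology are
#' rebuilt from the matched shear moduli.
#'
#' For a series solid with shear moduli `G1`, `G2` and viscosity `eta`,
#' the equivalent parallel solid has relaxed branch `G1*G2/(G1+G2)`,
#' Maxwell branch `G1^2/(G1+G2)` and viscosity `G1^2*eta/(G1+G2)^2`
#' (preserving the relaxation rate `(G1+G2)/eta = G2_par/eta_par`).
#' The maps are mutually inverse on positive parameters.
#'
#' @param solid A [zener_series()] or [zener_parallel()] object.
#' @return The solid re-expressed in the other topology.
#' @examples
#' s <- zener_series(0.032, 0.0213, 12.4, v1 = 0.380829)
#' p <- as_zener_parallel(s)
#' # identical shear relaxation: instantaneous and relaxed moduli match
#' c(s$G1, p$G1 + p$G2)
#' @export
as_zener_parallel <- function(solid) {
  if (inherits(solid, "zener_parallel")) {
    return(solid)
  }
  stopifnot(inherits(solid, "zener_series"))
  if (solid$eta <= 0) {
    abort_domain("topology conversion requires `eta` > 0.")
  }
  G1 <- solid$G1
  G2 <- solid$G2
  g_rel <- G1 * G2 / (G1 + G2) # relaxed branch
  g_max <- G1^2 / (G1 + G2) # Maxwell branch
  eta_par <- g_max * solid$eta / (G1 + G2)
  zener_parallel(
    E1 = 2 * g_rel * (1 + solid$v1),
    E2 = 2 * g_max * (1 + solid$v2),
    eta = eta_par,
    v1 = solid$v1, v2 = solid$v2
  )
}

#' @rdname as_zener_parallel
#' @export
as_zener_series <- function(solid) {
  if (inherits(solid, "zener_series")) {
    return(solid)
  }
  stopifnot(inherits(solid, "zener_parallel"))
  if (solid$eta <= 0) {
    abort_domain("topology conversion requires `eta` > 0.")
  }
  g_rel <- solid$G1
  g_max <- solid$G2
  G1 <- g_rel + g_max # instantaneous shear modulus
  G2 <- G1 * g_rel / g_max # series KV spring
  eta_ser <- (G1 + G2) * solid$eta / g_max
  zener_series(
    E1 = 2 * G1 * (1 + solid$v1),
    E2 = 2 * G2 * (1 + solid$v2),
    eta = eta_ser,
    v1 = solid$v1, v2 = solid$v2
  )
}
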