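#' Tip-sample contact configuration
#'
#' Bundles the geometry and adhesion of an AFM indentation experiment:
#' tip radius, cantilever spring constant, step relative approach, and
#' adhesion given either as an energy density `w` or as a measured
#' pull-off force (converted via [pull_off_to_adhesion()]). In the DMT
#' picture adhesion enters the force balance as a constant offset
#' `2*pi*w*R` (nN), the pull-off force.
#'
#' Units are nN / nm / GPa throughout (1 GPa = 1 nN/nm^2), so no
#' hidden conversion constants appear in the contact formulas.
#'
#' @param R Nominal tip/contact radius (nm).
#' @param k Cantilever spring constant (nN/nm).
#' @param D0 Step relative approach between cantilever end and
#'   substrate (nm); may be `NA` when not needed (e.g. loading fits).
#' @param w Adhesion energy density (nN/nm = J/m^2). Give exactly one
#'   of `w` and `pull_off`.
#' @param pull_off Measured pull-off force (nN).
#' @param convention Pull-off-to-adhesion conversion, `"dmt"`
#'   (default, `w = Fc/(2 pi R)`) or `"jkr"` (`w = 2 Fc/(3 pi R)`).
#' @return An object of class `"contact_config"` with fields `R`, `k`,
#'   `D0`, `w` and the derived `adhesion_term = 2*pi*w*R` (nN).
#' @examples
#' contact_config(R = 12, k = 5, D0 = 78.457, pull_off = 16)
#' @export
contact_config <- function(R, k, D0 = NA_real_, w = NULL, pull_off = NULL,
                           convention = c("dmt", "jkr")) {
  convention <- match.arg(convention)
  if (!is.numeric(R) || length(R) != 1L || !is.finite(R) || R <= 0) {
    abort_domain("tip radius `R` must be a single positive number (nm).")
  }
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0) {
    abort_domain("cantilever spring constant `k` must be a single positive number (nN/nm).")
  }
  if (!is.na(D0) && D0 <= 0) {
    abort_domain("relative approach `D0` must be positive (nm).")
  }
  if (is.null(w) == is.null(pull_off)) {
    abort_domain("give exactly one of `w` (adhesion energy density) or `pull_off` (force).")
  }
  if (is.null(w)) {
    if (pull_off < 0) abort_domain("`pull_off` must be non-negative (nN).")
    w <- pull_off_to_adhesion(pull_off, R, convention)
  }
  if (w < 0) abort_domain("adhesion energy density `w` must be non-negative (nN/nm).")
  structure(
    list(R = R, k = k, D0 = D0, w = w, adhesion_term = 2 * pi * w * R),
    class = "contact_config"
  )
}

#' @export
print.contact_config <- function(x, ...) {
  cat("<contact configuration>\n")
  cat(sprintf("  R = %g nm, k = %g nN/nm, D0 = %g nm\n", x$R, x$k, x$D0))
  cat(sprintf("  w = %g nN/nm  (adhesion offset 2*pi*w*R = %g nN)\n",
              x$w, x$adhesion_term))
  invisible(x)
}

reduced_modulus <- function(E, v) 4 * E / (3 * (1 - v^2))

need_D0 <- function(contact) {
  if (is.na(contact$D0)) {
    abort_domain("this operation requires the step relative approach `D0` in the contact configuration.")
  }
  invisible(contact)
}

# geometric prefactor of the step-approach force solution (nm^2;
# multiplies GPa-valued coefficients to give nN)
relaxation_prefactor <- function(contact) {
  need_D0(contact)
  (4 / 3) * contact$D0^1.5 * sqrt(contact$R)
}

#' Elastic DMT indentation force
#'
#' Adhesive spherical contact on an elastic half-space in the DMT
#' limit: \deqn{F + 2\pi w R = \delta^{3/2} E^* \sqrt{R}}, with
#' reduced modulus \eqn{E^* = 4E/(3(1-\nu^2))} (rigid tip). At zero
#' depth the net force is the adhesion pull `-2*pi*w*R`.
#'
#' @param E Sample Young's modulus (GPa).
#' @param v Sample Poisson ratio.
#' @param contact A [contact_config()].
#' @param delta Indentation depth (nm), non-negative; vectorized.
#' @return Force (nN).
#' @examples
#' cc <- contact_config(R = 12, k = 5, pull_off = 16)
#' dmt_elastic_force(E = 2.14, v = 0.380829, cc, delta = 10)
#' @export
dmt_elastic_force <- function(E, v, contact, delta) {
  stopifnot(inherits(contact, "contact_config"))
  if (any(!is.finite(delta)) || any(delta < 0)) {
    abort_domain("indentation depth `delta` must be finite and non-negative.")
  }
  delta^1.5 * reduced_modulus(E, v) * sqrt(contact$R) - contact$adhesion_term
}

#' Z-piezo displacement of an elastic DMT loading curve
#'
#' Inverse of the DMT relation including the cantilever in series:
#' \deqn{z = F/k + \big((F + 2\pi w R)/(E^* \sqrt{R})\big)^{2/3},}
#' the Z-piezo displacement being cantilever deflection plus sample
#' deformation.
#'
#' @inheritParams dmt_elastic_force
#' @param force Applied force (nN); `force + 2*pi*w*R` must be
#'   non-negative (the pre-contact regime is not modeled).
#' @return Displacement z (nm).
#' @export
loading_displacement <- function(E, v, contact, force) {
  stopifnot(inherits(contact, "contact_config"))
  total <- force + contact$adhesion_term
  if (any(!is.finite(total)) || any(total < 0)) {
    abort_domain("`force + 2*pi*w*R` must be non-negative (pre-contact regime not modeled).")
  }
  force / contact$k + (total / (reduced_modulus(E, v) * sqrt(contact$R)))^(2 / 3)
}

#' Coefficients of the closed-form force-relaxation solution
#'
#' Under a step relative approach `D0` the viscoelastic DMT contact
#' force is
#' \deqn{F(t) = \tfrac{4}{3}\sqrt{D_0^3 R}\,
#'   (A_r e^{-\alpha t} + B_r e^{-\beta t} + C_r) - 2\pi w R,}
#' with coefficients (series standard solid, elastic bulk response)
#' \deqn{A_r = \frac{G_1^2}{G_1+G_2}, \quad
#'  B_r = \frac{27 G_1^2 K_1^2}{(3K_1+4G_1)(3K_1G_1+3K_1G_2+4G_1G_2)},}
#' \deqn{C_r = \frac{4G_1G_2}{G_1+G_2}
#'   \Big(1 - \frac{3G_1G_2}{3K_1G_1+3K_1G_2+4G_1G_2}\Big), \quad
#'  \alpha = \frac{G_1+G_2}{\eta}, \quad
#'  \beta = \frac{G_2}{\eta} + \frac{3K_1G_1}{\eta(3K_1+4G_1)}.}
#' These are exactly the partial fractions of the operator rational
#' function `B(s)/(s A(s))` of [operator_coefficients()]. Two
#' consistency identities pin the limits: `Ar+Br+Cr = E1/(1-v1^2)`
#' (instantaneous elastic response) and `Cr = E_eq/(1-v_eq^2)` built
#' from the relaxed shear and elastic bulk moduli.
#'
#' @param solid A [zener_series()] solid with `eta > 0`.
#' @param contact A [contact_config()] with `D0` set.
#' @return An object of class `"relaxation_coefficients"`: list with
#'   `Ar`, `Br`, `Cr` (GPa), `alpha`, `beta` (1/ms) and `prefactor`
#'   (nm^2).
#' @examples
#' sc <- tmv_scenario()
#' relaxation_coefficients(sc$solid, sc$contact)
#' @export
relaxation_coefficients <- function(solid, contact) {
  if (!inherits(solid, "zener_series")) {
    abort_domain("`solid` must be a series-topology standard solid.")
  }
  stopifnot(inherits(contact, "contact_config"))
  if (solid$eta <= 0) {
    abort_domain("force relaxation requires `eta` > 0 (use the elastic DMT functions otherwise).")
  }
  G1 <- solid$G1
  G2 <- solid$G2
  K1 <- solid$K1
  eta <- solid$eta
  mix <- 3 * K1 * G1 + 3 * K1 * G2 + 4 * G1 * G2
  structure(
    list(
      Ar = G1^2 / (G1 + G2),
      Br = 27 * G1^2 * K1^2 / ((3 * K1 + 4 * G1) * mix),
      Cr = 4 * G1 * G2 / (G1 + G2) * (1 - 3 * G1 * G2 / mix),
      alpha = (G1 + G2) / eta,
      beta = G2 / eta + 3 * K1 * G1 / (eta * (3 * K1 + 4 * G1)),
      prefactor = relaxation_prefactor(contact)
    ),
    class = "relaxation_coefficients"
  )
}

#' @export
print.relaxation_coefficients <- function(x, ...) {
  cat("<force-relaxation coefficients>\n")
  cat(sprintf("  Ar = %.6g, Br = %.6g, Cr = %.6g GPa\n", x$Ar, x$Br, x$Cr))
  cat(sprintf("  alpha = %.6g, beta = %.6g 1/ms\n", x$alpha, x$beta))
  cat(sprintf("  prefactor = %.6g nm^2\n", x$prefactor))
  invisible(x)
}

#' Viscoelastic indentation force relaxation under a step approach
#'
#' Evaluates the closed-form solution documented in
#' [relaxation_coefficients()]: the indentation force decays from the
#' instantaneous elastic DMT value (set by `E1`) to the relaxed
#' asymptote (set by the relaxed moduli) as the sample creeps under
#' the fixed cantilever-end position.
#'
#' @inheritParams relaxation_coefficients
#' @param t Time since the step (ms), non-negative; vectorized.
#' @return Force (nN).
#' @examples
#' sc <- tmv_scenario()
#' force_relaxation(sc$solid, sc$contact, t = c(0, 1000, 5000))
#' @export
force_relaxation <- function(solid, contact, t) {
  check_time(t)
  co <- relaxation_coefficients(solid, contact)
  co$prefactor * (co$Ar * exp(-co$alpha * t) + co$Br * exp(-co$beta * t) + co$Cr) -
    contact$adhesion_term
}

#' Force relaxation predicted from sample-only moduli
#'
#' The combined fit of a relaxation curve describes cantilever and
#' sample in series; simulating the response of the sample alone
#' substitutes the sample's instantaneous shear modulus `G1s` (from
#' the loading-curve modulus `E1s`) for the combined `G1` in the
#' force-relaxation coefficients. With a stiff sample the relaxed
#' asymptote `prefactor*Cr - 2*pi*w*R` can be negative, i.e. a net
#' attractive force; for very compliant samples it stays positive.
#'
#' A series-topology solid carrying the sample parameters (`E1s`,
#' `E2s`, `eta_s`) is used directly; a parallel-topology solid is
#' accepted by reading its parameter triplet into the same
#' coefficient formulas (the two topologies share the triplet in this
#' treatment, where the cantilever affects only the instantaneous
#' spring), not by a topological conversion.
#'
#' @param sample A [zener_series()] (or [zener_parallel()], see
#'   Details) solid carrying the sample-only parameters.
#' @inheritParams force_relaxation
#' @return Force (nN).
#' @export
force_relaxation_sample_only <- function(sample, contact, t) {
  if (inherits(sample, "zener_parallel")) {
    sample <- zener_series(sample$E1, sample$E2, sample$eta, sample$v1, sample$v2)
  }
  force_relaxation(sample, contact, t)
}

#' Indentation depth creep under a step force
#'
#' Solves the operator form of the adhesive contact equation for the
#' depth history when a step force `F0` is applied at t = 0: in the
#' Laplace domain \eqn{\widehat{\delta^{3/2}}(s) =
#' \frac{3(F_0+2\pi wR)}{4\sqrt{R}} \frac{A(s)}{s B(s)}}, whose exact
#' partial-fraction inverse is a constant plus two decaying
#' exponentials,
#' \deqn{\delta^{3/2}(t) = \frac{3(F_0+2\pi wR)}{4\sqrt{R}}
#'   \big(c_0 + c_1 e^{-\lambda_1 t} + c_2 e^{-\lambda_2 t}\big),}
#' with rates \eqn{\lambda_1 = G_2/\eta} (the Kelvin-Voigt pole) and
#' \eqn{\lambda_2 = (G_1G_2 + 3K_1(G_1+G_2))/(\eta(G_1+3K_1))}. At t =
#' 0 the depth equals the elastic DMT depth at the instantaneous
#' moduli; at long times it approaches the relaxed elastic depth
#' (`c_0 = 1/Cr`). The closed form is cross-checked at construction
#' against the numerical Laplace oracle ([laplace_creep_oracle()]);
#' a divergence beyond `check_tol` raises a warning carrying the
#' observed discrepancy.
#'
#' @param sample A [zener_series()] solid carrying the sample
#'   parameters (the step force acts on the sample directly, so the
#'   cantilever spring is not part of this model).
#' @param contact A [contact_config()] (only `R` and the adhesion
#'   term are used).
#' @param F0 Step force (nN); `F0 + 2*pi*w*R` must be positive.
#' @param t Time (ms), non-negative; vectorized.
#' @param check_tol Relative tolerance of the construction-time oracle
#'   cross-check (set `Inf` to skip).
#' @return A tibble of class `"creep_solution"` with columns `time_ms`
#'   and `depth_nm`, and attributes `F0`, `terms` (the partial-fraction
#'   coefficients) and `oracle_check` (max relative divergence seen).
#' @examples
#' sc <- tmv_scenario()
#' indentation_creep(sc$sample_series, sc$contact, F0 = 50, t = c(0, 10, 100))
#' @export
indentation_creep <- function(sample, contact, F0, t, check_tol = 1e-3) {
  if (!inherits(sample, "zener_series")) {
    abort_domain("`sample` must be a series-topology standard solid.")
  }
  stopifnot(inherits(contact, "contact_config"))
  check_time(t)
  total <- F0 + contact$adhesion_term
  if (!is.finite(total) || total <= 0) {
    abort_domain("total load `F0 + 2*pi*w*R` must be positive.")
  }
  ops <- operator_coefficients(sample)
  terms <- step_response_terms(ops$A, ops$B) # L^{-1}[A/(s B)], units 1/GPa
  load_factor <- 3 * total / (4 * sqrt(contact$R))
  d32 <- load_factor * eval_step_response(terms, t)
  depth <- d32^(2 / 3)
  oracle_div <- NA_real_
  if (is.finite(check_tol)) {
    t_chk <- c(1, 50, 1000)
    d_closed <- (load_factor * eval_step_response(terms, t_chk))^(2 / 3)
    d_oracle <- laplace_creep_oracle(sample, contact, F0, t_chk)
    oracle_div <- max(abs(d_closed - d_oracle) / abs(d_oracle))
    if (oracle_div > check_tol) {
      rlang::warn(
        sprintf(
          "creep closed form diverges from the numerical Laplace oracle (max relative %.3g > %.3g).",
          oracle_div, check_tol
        ),
        class = "afmvisc_oracle_divergence"
      )
    }
  }
  out <- tibble::tibble(time_ms = t, depth_nm = depth)
  class(out) <- c("creep_solution", class(out))
  attr(out, "F0") <- F0
  attr(out, "terms") <- terms
  attr(out, "oracle_check") <- oracle_div
  out
}

# Laplace transform of the step-approach force solution (rational
# form assembled from the operator polynomials); real or complex s
force_relaxation_laplace <- function(solid, contact, include_adhesion = TRUE) {
  ops <- operator_coefficients(solid)
  pref <- relaxation_prefactor(contact)
  adh <- contact$adhesion_term
  function(s) {
    val <- pref * poly_eval(ops$B, s) / (s * poly_eval(ops$A, s))
    if (include_adhesion) val - adh / s else val
  }
}

#' Numerical Laplace-inversion oracle for force relaxation
#'
#' Solves the Laplace-domain contact equation
#' \eqn{A(s)(\widehat F + 2\pi wR/s) = \tfrac{4\sqrt R}{3} D_0^{3/2}
#' B(s)/s} for \eqn{\widehat F(s)} and inverts it numerically
#' ([invert_laplace()]). Independent of the partial-fraction closed
#' form in [force_relaxation()]; used to validate it.
#'
#' @inheritParams force_relaxation
#' @param t Time (ms), strictly positive.
#' @return Force (nN).
#' @export
laplace_forward_oracle <- function(solid, contact, t) {
  if (!inherits(solid, "zener_series")) {
    abort_domain("`solid` must be a series-topology standard solid.")
  }
  stopifnot(inherits(contact, "contact_config"))
  if (any(t <= 0)) abort_domain("the numerical oracle requires t > 0.")
  fhat <- force_relaxation_laplace(solid, contact, include_adhesion = FALSE)
  invert_laplace(fhat, t) - contact$adhesion_term
}

#' Numerical Laplace-inversion oracle for indentation creep
#'
#' Inverts \eqn{\widehat{\delta^{3/2}}(s) = \frac{3(F_0+2\pi
#' wR)}{4\sqrt R} A(s)/(s B(s))} numerically and takes the 2/3 power.
#' Independent of the partial-fraction route in
#' [indentation_creep()].
#'
#' @inheritParams indentation_creep
#' @param t Time (ms), strictly positive.
#' @return Depth (nm).
#' @export
laplace_creep_oracle <- function(sample, contact, F0, t) {
  if (!inherits(sample, "zener_series")) {
    abort_domain("`sample` must be a series-topology standard solid.")
  }
  stopifnot(inherits(contact, "contact_config"))
  if (any(t <= 0)) abort_domain("the numerical oracle requires t > 0.")
  total <- F0 + contact$adhesion_term
  if (total <= 0) abort_domain("total load `F0 + 2*pi*w*R` must be positive.")
  ops <- operator_coefficients(sample)
  load_factor <- 3 * total / (4 * sqrt(contact$R))
  fhat <- function(s) load_factor * poly_eval(ops$A, s) / (s * poly_eval(ops$B, s))
  d32 <- invert_laplace(fhat, t)
  d32^(2 / 3)
}

#' Indentation-depth / sample-size quality check
#'
#' Half-space contact models stop being trustworthy once the
#' indentation depth is an appreciable fraction of the sample size:
#' beyond a depth-to-height ratio of 10% the stiff substrate
#' contributes to the measured stiffness. Returns a QC record;
#' flagged runs should be re-measured at lower force or interpreted
#' with a substrate correction.
#'
#' @param depth_max Maximum indentation depth reached (nm).
#' @param sample_height Sample height/diameter along the indentation
#'   axis (nm).
#' @param threshold Flag ratio, default 0.10.
#' @return A tibble with columns `depth_max_nm`, `sample_height_nm`,
#'   `ratio`, `flagged` and `message`.
#' @examples
#' validate_indentation(13.2, 300)
#' @export
validate_indentation <- function(depth_max, sample_height, threshold = 0.10) {
  if (depth_max <= 0 || sample_height <= 0) {
    abort_domain("`depth_max` and `sample_height` must be positive.")
  }
  ratio <- depth_max / sample_height
  flagged <- ratio >= threshold
  tibble::tibble(
    depth_max_nm = depth_max,
    sample_height_nm = sample_height,
    ratio = ratio,
    flagged = flagged,
    message = if (flagged) {
      sprintf("indentation depth is %.1f%% of the sample height (>= %.0f%%): substrate effect not negligible.",
              100 * ratio, 100 * threshold)
    } else {
      "substrate effect negligible at this depth."
    }
  )
}
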