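#' Convert a measured pull-off force to an adhesion energy density
#'
#' In adhesive contact the maximum attractive force at separation
#' (the pull-off force `Fc`) fixes the adhesion energy density `w`.
#' The DMT convention, used throughout this package's force balance,
#' is `Fc = 2*pi*w*R`; the JKR convention `Fc = 3*pi*w*R/2` is
#' available for comparison with JKR-based reports.
#'
#' @param Fc Mean pull-off force (nN), non-negative.
#' @param R Tip radius (nm).
#' @param convention `"dmt"` (default) or `"jkr"`.
#' @return Adhesion energy density `w` (nN/nm = J/m^2).
#' @examples
#' pull_off_to_adhesion(16, 12) # the DMT value
#' @export
pull_off_to_adhesion <- function(Fc, R, convention = c("dmt", "jkr")) {
  convention <- match.arg(convention)
  if (!is.numeric(Fc) || Fc < 0) abort_domain("`Fc` must be non-negative (nN).")
  if (!is.numeric(R) || R <= 0) abort_domain("`R` must be positive (nm).")
  switch(convention,
    dmt = Fc / (2 * pi * R),
    jkr = 2 * Fc / (3 * pi * R)
  )
}

new_afm_fit <- function(subclass, estimates, fitted, residuals, r_squared,
                        method, curve, contact, warnings = character()) {
  structure(
    list(
      estimates = estimates,
      fitted = fitted,
      residuals = residuals,
      r_squared = r_squared,
      method = method,
      curve = curve,
      contact = contact,
      warnings = warnings
    ),
    class = c(subclass, "afm_fit")
  )
}

#' @export
print.afm_fit <- function(x, ...) {
  cat(sprintf("<AFM force-curve fit: %s>\n", x$method))
  if (!is.null(x$solid)) print(x$solid)
  for (nm in names(x$estimates)) {
    cat(sprintf("  %s = %g\n", nm, x$estimates[[nm]]))
  }
  cat(sprintf("  R^2 = %.6f on %d points\n", x$r_squared, length(x$residuals)))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

# accepts an afm_curve or a plain data frame with the canonical
# columns (sorted internally, so row order is immaterial)
check_relaxation_curve <- function(curve, min_points) {
  if (!inherits(curve, "afm_curve")) {
    if (is.data.frame(curve) && all(c("time_ms", "force_nN") %in% names(curve))) {
      ord <- order(curve$time_ms)
      curve <- afm_curve(curve$time_ms[ord], curve$force_nN[ord], kind = "relaxation")
    } else {
      abort_data("`curve` must be a relaxation force curve (columns time_ms, force_nN).")
    }
  }
  if (curve_kind(curve) != "relaxation") {
    abort_data("`curve` must be a relaxation force curve (columns time_ms, force_nN).")
  }
  if (nrow(curve) < min_points) {
    abort_data(sprintf("at least %d points are required for this fit.", min_points))
  }
  curve
}

relax_model <- function(par, v1, v2, contact, t) {
  # par = c(E1, E2, eta) in GPa / GPa / GPa ms
  force_relaxation(zener_series(par[1], par[2], par[3], v1, v2), contact, t)
}

# plateau statistics from the tail of a relaxation curve; the
# flatness test compares the tail mean with the mean of the preceding
# window so that point-to-point measurement noise (estimated from
# first differences of the tail) does not masquerade as a trend
plateau_stats <- function(tms, force, plateau_fraction) {
  n <- length(tms)
  n_tail <- max(2L, ceiling(plateau_fraction * n))
  tail_idx <- seq(n - n_tail + 1L, n)
  prev_idx <- seq(max(1L, n - 2L * n_tail + 1L), n - n_tail)
  flat_idx <- c(prev_idx, tail_idx)
  noise_sd <- if (length(flat_idx) >= 4) stats::sd(diff(force[flat_idx])) / sqrt(2) else 0
  trend <- abs(mean(force[tail_idx]) - mean(force[prev_idx]))
  trend_se <- noise_sd * sqrt(1 / n_tail + 1 / length(prev_idx))
  list(
    idx = tail_idx,
    f_inf = mean(force[tail_idx]),
    trend = trend,
    trend_allowance = 4 * trend_se
  )
}

# decay-rate estimate by log-linear regression on the early transient
log_linear_rate <- function(tms, force, f_inf, drop) {
  above <- which(force - f_inf > 0.1 * drop & tms > 0)
  if (length(above) < 2) {
    return(NA_real_)
  }
  fit <- stats::lm(log(force[above] - f_inf) ~ tms[above])
  rate <- -unname(stats::coef(fit)[2])
  if (!is.finite(rate) || rate <= 0) NA_real_ else rate
}

# initial force by extrapolating a two-exponential + plateau pre-fit
# (first samples can carry contact transients, so the raw first point
# is only the fallback)
estimate_initial_force <- function(tms, force, f_inf, drop, rate_hat) {
  f0_raw <- force[1]
  if (!is.finite(rate_hat)) {
    return(f0_raw)
  }
  # two exponentials plus a free plateau constant: the model family of
  # the relaxation solution itself, so on clean data the extrapolated
  # initial force is exact to optimizer tolerance
  res_fn <- function(p) force - (p[5] + exp(p[1]) * exp(-exp(p[3]) * tms) +
                                   exp(p[2]) * exp(-exp(p[4]) * tms))
  start <- c(log(c(drop / 2, drop / 2, rate_hat, rate_hat / 2)), f_inf)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = res_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 400, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(f0_raw)
  }
  f0 <- fit$par[5] + exp(fit$par[1]) + exp(fit$par[2])
  if (!is.finite(f0) || f0 < f_inf || f0 > f_inf + 5 * drop) f0_raw else f0
}

# invert the relaxed-limit identity Cr = 4G(3K1+G)/(3K1+4G) for the
# relaxed shear modulus G, given the instantaneous K1
relaxed_shear_from_cr <- function(Cr, K1) {
  # 4G^2 + (12 K1 - 4 Cr) G - 3 Cr K1 = 0, positive root
  b <- 12 * K1 - 4 * Cr
  (-b + sqrt(b^2 + 48 * Cr * K1)) / 8
}

#' Three-point extraction of viscoelastic parameters from a relaxation curve
#'
#' Solves for the series standard-solid parameters (`E1`, `E2`,
#' `eta`) from three statistics of a force-time relaxation curve: the
#' initial force, the plateau force, and one intermediate point.
#' `E1` follows from the instantaneous force (the sum `Ar+Br+Cr`
#' equals `E1/(1-v1^2)`); the plateau fixes `Cr` and hence the
#' relaxed shear modulus, giving `E2`; the intermediate point then
#' determines `eta` by one-dimensional root finding. The three
#' resulting nonlinear equations are polished by a damped
#' Gauss-Newton step so that on noiseless model data the generator
#' parameters are recovered to near machine precision.
#'
#' The plateau force is the mean of the final `plateau_fraction` of
#' samples; the fit refuses curves whose tail still varies by more
#' than 1% of the total drop (hold longer delay times in that case).
#' The intermediate point is the sample closest to the estimated
#' fast relaxation time `1/alpha`, where the sensitivity to `eta` is
#' greatest; a curve whose candidate point already sits on the
#' plateau is rejected as ill-conditioned. The initial force is
#' extrapolated from a two-exponential pre-fit rather than read off
#' the first raw sample.
#'
#' @param curve A relaxation [afm_curve()] (>= 3 points).
#' @param contact A [contact_config()] with `D0` set.
#' @param v1,v2 Poisson ratios assumed for the two springs (`v2`
#'   defaults to `v1`). Not identifiable from a single force curve,
#'   so they are inputs.
#' @param plateau_fraction Fraction of trailing samples averaged for
#'   the plateau force (default 0.1).
#' @return An object of classes `"afm_relaxation_fit"`, `"afm_fit"`:
#'   fitted `$solid` ([zener_series()]), `$r_squared`, per-point
#'   `$residuals` (nN), `$method`, `$warnings`. Use [tidy()] /
#'   [glance()] / [augment()] for tabular views.
#' @examples
#' sc <- tmv_scenario()
#' curve <- generate_relaxation_curve(sc$solid, sc$contact)
#' fit_three_point(curve, sc$contact, v1 = sc$v)
#' @export
fit_three_point <- function(curve, contact, v1, v2 = v1, plateau_fraction = 0.1) {
  curve <- check_relaxation_curve(curve, 3L)
  stopifnot(inherits(contact, "contact_config"))
  tms <- curve$time_ms
  force <- curve$force_nN
  warnings <- character()

  pl <- plateau_stats(tms, force, plateau_fraction)
  drop <- max(force) - pl$f_inf
  if (drop <= 0 || drop <= 1e-9 * max(abs(force))) {
    abort_fit("the curve shows no force drop: the retarded spring `E2` is unidentifiable.")
  }
  if (pl$trend >= max(0.01 * drop, pl$trend_allowance)) {
    abort_fit(paste0(
      "no plateau: the final ", round(100 * plateau_fraction),
      "% of samples still drift by more than 1% of the total force drop. ",
      "Acquire longer delay times."
    ))
  }

  rate_hat <- log_linear_rate(tms, force, pl$f_inf, drop)
  f0_hat <- estimate_initial_force(tms, force, pl$f_inf, drop, rate_hat)

  pref <- relaxation_prefactor(contact)
  adh <- contact$adhesion_term
  E1 <- (f0_hat + adh) / pref * (1 - v1^2)
  if (E1 <= 0) abort_fit("non-physical instantaneous force: fitted E1 <= 0.")
  G1 <- shear_modulus(E1, v1)
  K1 <- bulk_modulus(E1, v1)
  Cr_hat <- (pl$f_inf + adh) / pref
  g_rel <- relaxed_shear_from_cr(Cr_hat, K1)
  if (!is.finite(g_rel) || g_rel <= 0 || g_rel >= G1) {
    abort_fit("plateau force is inconsistent with the instantaneous force (relaxed modulus must lie below the instantaneous one).")
  }
  G2 <- G1 * g_rel / (G1 - g_rel)
  E2 <- 2 * G2 * (1 + v2)

  # intermediate point: nearest sample to the fast relaxation time
  t_pos <- which(tms > 0)
  if (!is.finite(rate_hat)) rate_hat <- 1 / stats::median(tms[t_pos])
  i_mid <- t_pos[which.min(abs(tms[t_pos] - 1 / rate_hat))]
  if (force[i_mid] - pl$f_inf < 0.05 * drop) {
    abort_fit("the intermediate point lies on the plateau: the curve is ill-conditioned for the viscosity. Sample earlier delay times.")
  }
  t_mid <- tms[i_mid]
  f_mid <- force[i_mid]

  gap <- function(log10_eta) {
    relax_model(c(E1, E2, 10^log10_eta), v1, v2, contact, t_mid) - f_mid
  }
  lo <- -6
  hi <- 6
  eta <- if (gap(lo) * gap(hi) < 0) {
    10^stats::uniroot(gap, c(lo, hi), tol = 1e-12)$root
  } else {
    warnings <- c(warnings, "intermediate point outside the model envelope; viscosity initialized from the log-linear rate.")
    (G1 + G2) / rate_hat
  }

  # polish: solve the exactly-determined three-point system
  tail_t <- tms[pl$idx]
  tail_mean <- mean(force[pl$idx])
  res_fn <- function(p) {
    par <- exp(p)
    c(
      relax_model(par, v1, v2, contact, 0) - f0_hat,
      relax_model(par, v1, v2, contact, t_mid) - f_mid,
      mean(relax_model(par, v1, v2, contact, tail_t)) - tail_mean
    )
  }
  polish <- tryCatch(
    minpack.lm::nls.lm(par = log(c(E1, E2, eta)), fn = res_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) NULL
  )
  if (!is.null(polish) && all(is.finite(polish$par))) {
    par <- exp(polish$par)
    E1 <- par[1]
    E2 <- par[2]
    eta <- par[3]
  } else {
    warnings <- c(warnings, "three-point polish step failed; sequential estimates reported.")
  }

  solid <- zener_series(E1, E2, eta, v1, v2)
  fitted <- force_relaxation(solid, contact, tms)
  residuals <- force - fitted
  r2 <- 1 - sum(residuals^2) / sum((force - mean(force))^2)
  out <- new_afm_fit("afm_relaxation_fit",
    estimates = list(E1_GPa = E1, E2_GPa = E2, eta_GPa_ms = eta),
    fitted = fitted, residuals = residuals, r_squared = r2,
    method = "three_point", curve = curve, contact = contact,
    warnings = warnings
  )
  out$solid <- solid
  out
}

#' Least-squares extraction of viscoelastic parameters
#'
#' Damped (Levenberg-Marquardt) nonlinear least squares of the
#' force-relaxation closed form over (`E1`, `E2`, `eta`), using every
#' point of the curve. Parameters are optimized on the log scale
#' within physical-plausibility bounds (`E1`, `E2` in (1e-6, 1e3)
#' GPa, `eta` in (1e-6, 1e6) GPa ms); starting values come from
#' [fit_three_point()] unless `init` is supplied.
#'
#' @inheritParams fit_three_point
#' @param init Optional starting point: an `afm_relaxation_fit`, a
#'   [zener_series()] solid, or a numeric vector `c(E1, E2, eta)`.
#' @return An `afm_relaxation_fit` (see [fit_three_point()]) with
#'   `method = "least_squares"`.
#' @examples
#' sc <- tmv_scenario()
#' curve <- generate_relaxation_curve(sc$solid, sc$contact,
#'   noise = noise_spec(sd = 1, seed = 1)
#' )
#' fit_least_squares(curve, sc$contact, v1 = sc$v)
#' @export
fit_least_squares <- function(curve, contact, v1, v2 = v1, init = NULL,
                              plateau_fraction = 0.1) {
  curve <- check_relaxation_curve(curve, 5L)
  stopifnot(inherits(contact, "contact_config"))
  tms <- curve$time_ms
  force <- curve$force_nN
  warnings <- character()

  start <- if (is.null(init)) {
    fit0 <- tryCatch(
      fit_three_point(curve, contact, v1, v2, plateau_fraction),
      error = function(e) NULL
    )
    if (is.null(fit0)) {
      warnings <- c(warnings, "three-point initialization failed; starting from scale heuristics.")
      pref <- relaxation_prefactor(contact)
      E1g <- max((max(force) + contact$adhesion_term) / pref * (1 - v1^2), 1e-5)
      c(E1g, E1g / 2, 10)
    } else {
      unlist(fit0$estimates, use.names = FALSE)
    }
  } else if (inherits(init, "afm_fit")) {
    unlist(init$estimates, use.names = FALSE)
  } else if (inherits(init, "zener_series")) {
    c(init$E1, init$E2, init$eta)
  } else {
    as.numeric(init)
  }

  lower <- log(c(1e-6, 1e-6, 1e-6))
  upper <- log(c(1e3, 1e3, 1e6))
  start_l <- pmin(pmax(log(start), lower), upper)
  res_fn <- function(p) force - relax_model(exp(p), v1, v2, contact, tms)
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = start_l, fn = res_fn, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15, ptol = 1e-15)
    ),
    error = function(e) abort_fit(paste0("least-squares fit failed to converge: ", conditionMessage(e)))
  )
  if (fit$info == 0) {
    abort_fit(paste0("least-squares fit did not converge: ", fit$message))
  }
  at_bound <- abs(fit$par - lower) < 1e-8 | abs(fit$par - upper) < 1e-8
  if (any(at_bound)) {
    warnings <- c(warnings, paste0(
      "parameter(s) at optimizer bounds: ",
      paste(c("E1", "E2", "eta")[at_bound], collapse = ", ")
    ))
  }
  par <- exp(fit$par)
  solid <- zener_series(par[1], par[2], par[3], v1, v2)
  fitted <- force_relaxation(solid, contact, tms)
  residuals <- force - fitted
  r2 <- 1 - sum(residuals^2) / sum((force - mean(force))^2)
  out <- new_afm_fit("afm_relaxation_fit",
    estimates = list(E1_GPa = par[1], E2_GPa = par[2], eta_GPa_ms = par[3]),
    fitted = fitted, residuals = residuals, r_squared = r2,
    method = "least_squares", curve = curve, contact = contact,
    warnings = warnings
  )
  out$solid <- solid
  out
}

#' Instantaneous modulus from a DMT loading curve
#'
#' One-parameter least squares of the elastic loading relation
#' `z = F/k + ((F + 2*pi*w*R)/(E* sqrt(R)))^(2/3)` over the reduced
#' modulus `E*`. Because the model is linear in `E*^(-2/3)` the
#' minimizer is available in closed form. Returns the instantaneous
#' Young's modulus `E1s = 3 E* (1 - v^2) / 4`.
#'
#' @param curve A loading [afm_curve()] (columns `z_nm`, `force_nN`);
#'   all forces must satisfy `F + 2*pi*w*R > 0`.
#' @param contact A [contact_config()] (uses `R`, `k` and the
#'   adhesion term; `D0` is not needed).
#' @param v_s Sample Poisson ratio.
#' @return An object of classes `"afm_loading_fit"`, `"afm_fit"` with
#'   estimates `E1s_GPa` and `E_star_GPa`, `$r_squared` on the
#'   displacement axis, and per-point `$residuals` (nm).
#' @examples
#' cc <- contact_config(R = 12, k = 5, pull_off = 16)
#' curve <- generate_loading_curve(2.14, 0.380829, cc, F_grid = seq(0, 100, 5))
#' fit_dmt_loading(curve, cc, v_s = 0.380829)
#' @export
fit_dmt_loading <- function(curve, contact, v_s) {
  if (!inherits(curve, "afm_curve")) {
    if (is.data.frame(curve) && all(c("z_nm", "force_nN") %in% names(curve))) {
      ord <- order(curve$z_nm)
      curve <- afm_curve(curve$z_nm[ord], curve$force_nN[ord], kind = "loading")
    } else {
      abort_data("`curve` must be a loading force curve (columns z_nm, force_nN).")
    }
  }
  if (curve_kind(curve) != "loading") {
    abort_data("`curve` must be a loading force curve (columns z_nm, force_nN).")
  }
  stopifnot(inherits(contact, "contact_config"))
  if (nrow(curve) < 2L) abort_data("at least 2 points are required.")
  force <- curve$force_nN
  z <- curve$z_nm
  total <- force + contact$adhesion_term
  if (all(total <= 0)) {
    abort_data("all forces lie below the adhesion offset: nothing in the contact regime to fit.")
  }
  if (any(total < 0)) {
    abort_data("some forces lie below `-2*pi*w*R`; the pre-contact regime is not modeled.")
  }
  # z - F/k = (total / sqrt(R))^(2/3) * E*^(-2/3): linear through origin
  y <- z - force / contact$k
  x <- (total / sqrt(contact$R))^(2 / 3)
  c_hat <- sum(x * y) / sum(x^2)
  if (c_hat <= 0) {
    abort_fit("loading curve slope is non-physical (sample deformation decreases with force).")
  }
  E_star <- c_hat^(-3 / 2)
  E1s <- 3 * E_star * (1 - v_s^2) / 4
  fitted <- loading_displacement(E1s, v_s, contact, force)
  residuals <- z - fitted
  r2 <- 1 - sum(residuals^2) / sum((z - mean(z))^2)
  out <- new_afm_fit("afm_loading_fit",
    estimates = list(E1s_GPa = E1s, E_star_GPa = E_star),
    fitted = fitted, residuals = residuals, r_squared = r2,
    method = "dmt_loading", curve = curve, contact = contact
  )
  out$v_s <- v_s
  out
}

#' Decouple cantilever and sample after the two fits
#'
#' The relaxation fit sees cantilever and sample in series, so its
#' instantaneous spring `E1` is the series combination of the
#' cantilever's effective modulus `E1c` and the sample's
#' instantaneous modulus `E1s`; the loading fit provides `E1s`
#' independently. Following the treatment in which the cantilever
#' affects only the instantaneous spring, the sample keeps the
#' combined fit's retarded spring and viscosity unchanged
#' (`E2s = E2`, `eta_s = eta`). The implied cantilever series modulus
#' `E1c = (1/E1 - 1/E1s)^(-1)` is reported alongside; note the map
#' from the spring constant `k` (nN/nm) to a modulus (GPa) is
#' geometry-dependent and is not claimed here.
#'
#' @param combined An `afm_relaxation_fit` of the combined
#'   cantilever+sample system.
#' @param E1s Instantaneous sample modulus (GPa), e.g. from
#'   [fit_dmt_loading()] (an `afm_loading_fit` may be passed
#'   directly).
#' @param v1s Poisson ratio for the sample's instantaneous spring;
#'   defaults to the combined fit's `v1`.
#' @return An object of class `"sample_properties"`: list with the
#'   sample parameter set in both topologies (`$series` as
#'   [zener_series()] for indentation predictions, `$parallel` as
#'   [zener_parallel()] for uniaxial and dynamic predictions --- the
#'   same parameter triplet read two ways, as in the underlying
#'   treatment), the implied `$E1c_GPa`, and `$warnings`.
#' @examples
#' sc <- tmv_scenario()
#' curve <- generate_relaxation_curve(sc$solid, sc$contact)
#' fit <- fit_least_squares(curve, sc$contact, v1 = sc$v)
#' assemble_sample_properties(fit, E1s = 2.14)
#' @export
assemble_sample_properties <- function(combined, E1s, v1s = NULL) {
  if (!inherits(combined, "afm_relaxation_fit")) {
    abort_domain("`combined` must be a relaxation fit.")
  }
  if (inherits(E1s, "afm_loading_fit")) E1s <- E1s$estimates$E1s_GPa
  solid <- combined$solid
  if (is.null(v1s)) v1s <- solid$v1
  warnings <- character()
  if (E1s < solid$E1) {
    abort_fit("inconsistent moduli: the sample spring `E1s` cannot be softer than the combined series spring `E1`.")
  }
  if (E1s == solid$E1) {
    warnings <- c(warnings, "E1s equals the combined E1: implies an infinitely stiff cantilever (degenerate decoupling).")
    E1c <- Inf
  } else {
    E1c <- 1 / (1 / solid$E1 - 1 / E1s)
  }
  warnings <- c(warnings,
    "cantilever assumed to affect only the instantaneous spring: E2s and eta_s taken unchanged from the combined fit.")
  structure(
    list(
      series = zener_series(E1s, solid$E2, solid$eta, v1s, solid$v2),
      parallel = zener_parallel(E1s, solid$E2, solid$eta, v1s, solid$v2),
      E1c_GPa = E1c,
      warnings = warnings
    ),
    class = "sample_properties"
  )
}

#' @export
print.sample_properties <- function(x, ...) {
  cat("<decoupled sample properties>\n")
  cat(sprintf("  E1s = %g GPa, E2s = %g GPa, eta_s = %g GPa ms\n",
              x$series$E1, x$series$E2, x$series$eta))
  cat(sprintf("  implied cantilever series modulus E1c = %g GPa\n", x$E1c_GPa))
  for (w in x$warnings) cat("  note:", w, "\n")
  invisible(x)
}
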