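#' Measurement-noise specification for synthetic curves
#'
#' Additive zero-mean Gaussian noise on the measured quantity is the
#' default instrument model; multiplicative noise (`sd` interpreted
#' as a relative standard deviation) is available as an option. With
#' a fixed `seed` the generated curve is bit-for-bit reproducible.
#'
#' @param sd Noise standard deviation: nN (additive, on force), nm
#'   (additive, on displacement), or a fraction of the signal
#'   (multiplicative). Default 0 (noiseless).
#' @param seed Integer RNG seed, or `NULL` to use the current RNG
#'   state.
#' @param model `"additive"` (default) or `"multiplicative"`.
#' @return An object of class `"noise_spec"`.
#' @examples
#' noise_spec(sd = 2, seed = 42)
#' @export
noise_spec <- function(sd = 0, seed = NULL, model = c("additive", "multiplicative")) {
  model <- match.arg(model)
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd < 0) {
    abort_domain("noise `sd` must be a single non-negative number.")
  }
  structure(list(sd = sd, seed = seed, model = model), class = "noise_spec")
}

apply_noise <- function(signal, noise) {
  stopifnot(inherits(noise, "noise_spec"))
  if (noise$sd == 0) {
    return(signal)
  }
  draw <- function() {
    eps <- stats::rnorm(length(signal), sd = noise$sd)
    if (noise$model == "additive") signal + eps else signal * (1 + eps)
  }
  if (is.null(noise$seed)) draw() else withr::with_seed(noise$seed, draw())
}

#' Default delay-time grid for relaxation curves
#'
#' The measured delay times (100, 200, 500, 1000 ms) preceded by
#' t = 0 and followed by a dense tail out to 5000 ms, by which time
#' the force has reached its plateau.
#'
#' @return Numeric vector of times (ms).
#' @export
default_t_grid <- function() {
  c(0, 100, 200, 500, 1000, seq(1500, 5000, by = 250))
}

#' Generate a synthetic force-relaxation curve
#'
#' Evaluates the closed-form force relaxation
#' ([force_relaxation()]) on a time grid and adds seeded measurement
#' noise, providing ground-truthed input for the fitting routines.
#'
#' @param solid A [zener_series()] solid (ground truth).
#' @param contact A [contact_config()] with `D0` set.
#' @param t_grid Non-negative, strictly increasing times (ms).
#' @param noise A [noise_spec()]; default noiseless.
#' @param id Optional curve id.
#' @return A relaxation [afm_curve()].
#' @examples
#' sc <- tmv_scenario()
#' generate_relaxation_curve(sc$solid, sc$contact,
#'   noise = noise_spec(sd = 2, seed = 7)
#' )
#' @export
generate_relaxation_curve <- function(solid, contact, t_grid = default_t_grid(),
                                      noise = noise_spec(), id = NULL) {
  check_time(t_grid)
  if (length(t_grid) >= 2 && any(diff(t_grid) <= 0)) {
    abort_data("`t_grid` must be strictly increasing.")
  }
  force <- force_relaxation(solid, contact, t_grid)
  afm_curve(t_grid, apply_noise(force, noise), kind = "relaxation", id = id)
}

#' Generate a synthetic DMT loading curve
#'
#' Evaluates the elastic loading relation ([loading_displacement()])
#' on a force grid and adds seeded measurement noise on the
#' displacement axis.
#'
#' @param E1s Instantaneous sample Young's modulus (GPa).
#' @param v_s Sample Poisson ratio.
#' @param contact A [contact_config()].
#' @param F_grid Strictly increasing forces (nN) with
#'   `F + 2*pi*w*R >= 0`.
#' @inheritParams generate_relaxation_curve
#' @return A loading [afm_curve()].
#' @export
generate_loading_curve <- function(E1s, v_s, contact, F_grid,
                                   noise = noise_spec(), id = NULL) {
  if (length(F_grid) >= 2 && any(diff(F_grid) <= 0)) {
    abort_data("`F_grid` must be strictly increasing.")
  }
  z <- loading_displacement(E1s, v_s, contact, F_grid)
  z <- apply_noise(z, noise)
  curve <- tibble::tibble(z_nm = z, force_nN = F_grid)
  # noise can break strict monotonicity of z; keep the tibble but tag it
  if (any(diff(z) <= 0)) {
    curve <- curve[order(curve$z_nm), ]
  }
  afm_curve(curve$z_nm, curve$force_nN, kind = "loading", id = id)
}

#' Study conditions of the TMV/Ba2+ superlattice experiment
#'
#' The fixed scenario used throughout examples and tests: the
#' combined cantilever+sample standard solid fitted from the
#' relaxation curve (`E1` = 32.0 MPa, `E2` = 21.3 MPa, `eta` = 12.4
#' GPa ms), the contact geometry (`D0` = 78.457 nm, `R` = 12 nm,
#' pull-off force 16 nN, `k` = 5 nN/nm), the sample instantaneous
#' modulus from the loading fit (`E1s` = 2.14 GPa), and the common
#' Poisson ratio `v` = 0.3808290 derived from consistency of the
#' fitted rate coefficient (`G1 + G2` = 19.3 MPa). Poisson ratios are
#' not independently measured; `v` is a documented, overridable
#' default.
#'
#' @param v Common Poisson ratio; default the consistency-derived
#'   value.
#' @return A list: `$solid` (combined, [zener_series()]), `$contact`
#'   ([contact_config()]), `$E1s` (GPa), `$sample_series` /
#'   `$sample_parallel` (sample-only parameter set in both
#'   topologies), `$v`, and `$t_grid` ([default_t_grid()]).
#' @examples
#' sc <- tmv_scenario()
#' force_relaxation(sc$solid, sc$contact, t = 0) # ~104 nN
#' @export
tmv_scenario <- function(v = (0.032 + 0.0213) / (2 * 0.0193) - 1) {
  contact <- contact_config(R = 12, k = 5, D0 = 78.457, pull_off = 16)
  solid <- zener_series(E1 = 0.032, E2 = 0.0213, eta = 12.4, v1 = v)
  E1s <- 2.14
  list(
    solid = solid,
    contact = contact,
    E1s = E1s,
    sample_series = zener_series(E1s, 0.0213, 12.4, v1 = v),
    sample_parallel = zener_parallel(E1s, 0.0213, 12.4, v1 = v),
    v = v,
    t_grid = default_t_grid()
  )
}
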