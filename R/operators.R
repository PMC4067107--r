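#' Viscoelastic differential-operator coefficients of the contact equation
#'
#' In the functional-equation (correspondence) treatment of adhesive
#' spherical contact, the elastic constants of the Hertz/DMT solution
#' are replaced by the linear differential operators of the material's
#' constitutive law. For the series standard solid with elastic
#' volumetric response the deviatoric operators are first order,
#'
#' \deqn{P^d = 1 + p_1^d \partial_t, \quad Q^d = q_0^d + q_1^d \partial_t,}
#'
#' with \eqn{p_1^d = \eta/(G_1+G_2)}, \eqn{q_0^d = 2G_1G_2/(G_1+G_2)},
#' \eqn{q_1^d = 2G_1\eta/(G_1+G_2)}, while the volumetric pair is
#' \eqn{P^m = 1}, \eqn{Q^m = 3K_1}. Substituting these into the reduced
#' modulus of the DMT relation yields a second-order differential
#' equation linking force and depth,
#' \deqn{\sum_i A_i \partial_t^i (F + 2\pi w R)
#'       = \tfrac{4\sqrt{R}}{3} \sum_i B_i \partial_t^i \delta^{3/2},}
#' whose coefficient polynomials are the operator products
#' \eqn{A(s) = P^d (2 Q^d + 3 K_1 P^d)} and
#' \eqn{B(s) = Q^d (Q^d + 6 K_1 P^d)}.
#'
#' @param solid A [zener_series()] solid.
#' @return An object of class `"zener_operators"`: list with `p1d`
#'   (ms), `q0d` (GPa), `q1d` (GPa ms), `K1` (GPa), and the polynomial
#'   coefficient vectors `A = c(A0, A1, A2)` and `B = c(B0, B1, B2)`
#'   (constant terms in GPa, higher orders scaled by ms per derivative
#'   order).
#' @examples
#' operator_coefficients(zener_series(0.032, 0.0213, 12.4, v1 = 0.380829))
#' @export
operator_coefficients <- function(solid) {
  if (!inherits(solid, "zener_series")) {
    abort_domain("`solid` must be a series-topology standard solid (see `zener_series()`).")
  }
  G1 <- solid$G1
  G2 <- solid$G2
  K1 <- solid$K1
  eta <- solid$eta
  p1d <- eta / (G1 + G2)
  q0d <- 2 * G1 * G2 / (G1 + G2)
  q1d <- 2 * G1 * eta / (G1 + G2)
  Pd <- c(1, p1d)
  Qd <- c(q0d, q1d)
  A <- 2 * poly_mul(Qd, Pd) + 3 * K1 * poly_mul(Pd, Pd)
  B <- poly_mul(Qd, Qd) + 6 * K1 * poly_mul(Pd, Qd)
  structure(
    list(p1d = p1d, q0d = q0d, q1d = q1d, K1 = K1, A = A, B = B),
    class = "zener_operators"
  )
}

#' @export
print.zener_operators <- function(x, ...) {
  cat("<contact operator coefficients>\n")
  cat(sprintf("  p1d = %g ms, q0d = %g GPa, q1d = %g GPa ms, K1 = %g GPa\n",
              x$p1d, x$q0d, x$q1d, x$K1))
  cat("  A:", format(x$A, digits = 6), "\n")
  cat("  B:", format(x$B, digits = 6), "\n")
  invisible(x)
}

# Partial-fraction expansion of N(s) / (s * D(s)) for quadratic (or
# degenerate lower-order) N, D with distinct negative real roots of D.
# Returns the step response L^{-1}[N/(s D)] as a constant plus
# exponential terms: value(t) = const + sum(amp * exp(-rate * t)).
step_response_terms <- function(num, den) {
  num <- c(num, numeric(3 - length(num)))
  den <- c(den, numeric(3 - length(den)))
  const <- num[1] / den[1]
  if (abs(den[3]) < .Machine$double.xmin) {
    if (abs(den[2]) < .Machine$double.xmin) {
      return(list(const = const, amp = numeric(0), rate = numeric(0)))
    }
    root <- -den[1] / den[2]
    amp <- poly_eval(num, root) / (root * den[2])
    return(list(const = const, amp = amp, rate = -root))
  }
  disc <- den[2]^2 - 4 * den[3] * den[1]
  if (disc <= 0) {
    abort_numeric("operator denominator has non-real roots; not a valid relaxation spectrum.")
  }
  roots <- c(
    (-den[2] - sqrt(disc)) / (2 * den[3]),
    (-den[2] + sqrt(disc)) / (2 * den[3])
  )
  dden <- den[2] + 2 * den[3] * roots # D'(root)
  amp <- poly_eval(num, roots) / (roots * dden)
  list(const = const, amp = amp, rate = -roots)
}

eval_step_response <- function(terms, t) {
  out <- rep(terms$const, length(t))
  for (i in seq_along(terms$amp)) {
    out <- out + terms$amp[i] * exp(-terms$rate[i] * t)
  }
  out
}

# ---- numerical inverse Laplace transforms -------------------------------

stehfest_weights <- function(N) {
  stopifnot(N %% 2 == 0)
  V <- numeric(N)
  for (k in seq_len(N)) {
    j <- floor((k + 1) / 2):min(k, N / 2)
    terms <- j^(N / 2) * factorial(2 * j) /
      (factorial(N / 2 - j) * factorial(j) * factorial(j - 1) *
         factorial(k - j) * factorial(2 * j - k))
    V[k] <- (-1)^(k + N / 2) * sum(terms)
  }
  V
}

stehfest_invert <- function(fhat, t, N = 14L) {
  V <- stehfest_weights(N)
  ln2 <- log(2)
  vapply(t, function(ti) {
    if (ti <= 0) abort_domain("Stehfest inversion requires t > 0.")
    s <- ln2 * seq_len(N) / ti
    sum(V * vapply(s, fhat, numeric(1))) * ln2 / ti
  }, numeric(1))
}

# fixed-Talbot contour inversion; fhat must accept complex s
talbot_invert <- function(fhat, t, M = 32L) {
  vapply(t, function(ti) {
    if (ti <= 0) abort_domain("Talbot inversion requires t > 0.")
    r <- 2 * M / (5 * ti)
    theta <- (seq_len(M - 1)) * pi / M
    s <- r * theta * (1 / tan(theta) + 1i)
    sigma <- theta + (theta / tan(theta) - 1) / tan(theta)
    terms <- Re(exp(ti * s) * vapply(s, fhat, complex(1)) * (1 + 1i * sigma))
    (r / M) * (0.5 * exp(r * ti) * Re(fhat(complex(real = r))) + sum(terms))
  }, numeric(1))
}

#' Numerically invert a Laplace-domain function
#'
#' Gaver-Stehfest inversion with an internal consistency check: the
#' result at 14 terms is compared with 12 and 16 terms, and if the
#' spread exceeds `self_tol` (relative) the routine falls back to a
#' fixed-Talbot contour evaluation (which requires `fhat` to accept
#' complex arguments). Intended for smooth, completely monotone
#' targets such as relaxation and creep transforms.
#'
#' @param fhat Function of the Laplace variable `s` (real for
#'   Stehfest; complex-capable for the Talbot fallback).
#' @param t Positive times at which to evaluate the inverse.
#' @param self_tol Relative Stehfest self-consistency tolerance.
#' @return Numeric vector, the inverse transform at `t`.
#' @examples
#' # L^{-1}[1/(s+1)] = exp(-t)
#' invert_laplace(function(s) 1 / (s + 1), t = c(0.5, 1, 2))
#' @export
invert_laplace <- function(fhat, t, self_tol = 1e-6) {
  check_time(t)
  if (any(t == 0)) abort_domain("numerical inversion requires t > 0.")
  v14 <- stehfest_invert(fhat, t, 14L)
  v12 <- stehfest_invert(fhat, t, 12L)
  v16 <- stehfest_invert(fhat, t, 16L)
  scale <- pmax(abs(v14), .Machine$double.eps)
  spread <- pmax(abs(v14 - v12), abs(v14 - v16)) / scale
  bad <- spread > self_tol
  if (any(bad)) {
    v14[bad] <- talbot_invert(fhat, t[bad])
  }
  v14
}
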