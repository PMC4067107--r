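---
title: "Transient viscoelastic analysis of adhesive AFM nanoindentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transient viscoelastic analysis of adhesive AFM nanoindentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afmvisc)
```

## The measurement and the model

`afmvisc` analyses transient AFM nanoindentation of soft, adhesive
nanomaterials — the motivating system is the hexagonally packed
tobacco mosaic virus (TMV)/Ba^2+^ superlattice, a rod-like virus
assembly a few hundred nanometres tall. Instead of oscillating the
tip, the transient protocol presses the tip to a target force, holds
the cantilever end at a fixed height for a programmed delay time, and
reads how much the force has relaxed as the sample creeps. A series of
such holds traces out a force--time relaxation curve from which both
elasticity and viscosity are extracted.

Three ingredients define the model:

1. **Adhesive elastic contact (DMT).** A rigid sphere of radius $R$
   on an elastic half-space with adhesion energy density $w$
   satisfies $F + 2\pi w R = \delta^{3/2} E^* \sqrt{R}$ with reduced
   modulus $E^* = 4E/(3(1-\nu^2))$. Adhesion enters only as the
   constant pull-off offset $2\pi w R$, which is what makes the
   viscoelastic extension tractable. JKR-style crack-edge adhesion is
   deliberately out of scope; the JKR pull-off convention is offered
   only when converting a measured pull-off force to $w$.

2. **Standard linear solid (Zener) material.** Two equivalent
   three-element topologies are kept as distinct types and never
   converted silently, because both are natural at different points
   of the analysis: `zener_series()` (spring $E_1$ in series with a
   Kelvin--Voigt element $E_2 \parallel \eta$) carries the
   instantaneous modulus $E_1$ and is what the contact solution is
   derived in; `zener_parallel()` (equilibrium spring in parallel
   with a Maxwell arm) gives the familiar uniaxial relaxation modulus
   $E_1 + E_2 e^{-E_2 t/\eta}$. Explicit converters
   (`as_zener_parallel()`, `as_zener_series()`) implement the exact
   shear-level matching and are bijective on positive parameters.
   The volumetric response is assumed elastic, governed by the bulk
   modulus $K_1$ of the instantaneous spring — the standard
   assumption that deviatoric flow, not volume change, carries the
   viscosity.

3. **The correspondence (functional-equation) method.** Replacing the
   elastic constants in the DMT relation by the material's
   differential operators $P^d = 1 + p_1^d \partial_t$,
   $Q^d = q_0^d + q_1^d \partial_t$ (deviatoric) and $P^m = 1$,
   $Q^m = 3K_1$ (volumetric) turns the contact relation into a
   second-order ODE linking force and depth, with polynomial
   coefficients $A(s) = P^d(2Q^d + 3K_1 P^d)$ and
   $B(s) = Q^d(Q^d + 6K_1 P^d)$ (`operator_coefficients()`).
   Quasi-static conditions are assumed throughout — inertial forces
   are neglected, which is appropriate at the millisecond-and-slower
   time scales of the hold protocol.

## Closed forms and their internal checks

**Force relaxation.** Under a step relative approach $D_0$ the
Laplace-domain solution is rational, and its exact inverse is

$$F(t) = \tfrac{4}{3}\sqrt{D_0^3 R}\,\big(A_r e^{-\alpha t} +
B_r e^{-\beta t} + C_r\big) - 2\pi w R ,$$

with all five coefficients explicit functions of $(G_1, G_2, K_1,
\eta)$ (`relaxation_coefficients()`). Two identities pin the limits
and are enforced as tests at $10^{-10}$ relative over randomized
parameter sweeps: $A_r + B_r + C_r = E_1/(1-\nu_1^2)$, so that $F(0)$
is exactly the elastic DMT force at the instantaneous moduli, and
$C_r = E_{eq}/(1-\nu_{eq}^2)$ built from the relaxed shear and
elastic bulk moduli, so that $F(\infty)$ is the relaxed elastic
force. One can also show $\alpha > \beta > 0$ for every valid solid,
so the force decays strictly monotonically.

**Indentation creep.** For a step force $F_0$ the same operator
equation gives $\widehat{\delta^{3/2}}(s) \propto A(s)/(s\,B(s))$.
The package inverts this exactly by partial fractions — a constant
plus two exponentials with rates $G_2/\eta$ and
$(G_1 G_2 + 3K_1(G_1+G_2))/(\eta\,(G_1 + 3K_1))$ — and raises the
result to the $2/3$ power (`indentation_creep()`). Because
coefficient algebra of this kind is error-prone, the closed form is
cross-checked *at construction time* against an independent numerical
Laplace inversion (`laplace_creep_oracle()`); a divergence beyond
`check_tol` is surfaced as a classed warning rather than silently
accepted. The analogous oracle for force relaxation
(`laplace_forward_oracle()`) agrees with the closed form to better
than $10^{-4}$ relative on $t \in [1, 5000]$ ms in the test suite.

**Numerical inversion.** `invert_laplace()` is Gaver--Stehfest with
14 terms, self-checked against 12- and 16-term evaluations; if the
spread exceeds $10^{-6}$ relative it falls back to a fixed-Talbot
contour evaluation. Stehfest suits these completely monotone, smooth
targets; the Talbot path covers small-magnitude tails where Stehfest
cancellation dominates. Closed forms are evaluated exactly at
$t = 0$; oracles are evaluated at $10^{-3}$ ms when a near-zero
comparison is needed, with a relaxed $10^{-3}$ tolerance.

**Dynamic moduli.** The Maxwell arm of the parallel solid gives

$$G'(\omega) = \frac{\omega^2 G_2 \eta^2}{G_2^2 + \omega^2\eta^2},
\qquad
G''(\omega) = \frac{G_2^2 \omega \eta}{G_2^2 + \omega^2\eta^2},$$

with $\eta$ converted internally from GPa·ms to GPa·s so $\omega$ is
in rad/s. By default the equilibrium spring $G_1$ is *not* added to
$G'$: only the decaying part of the relaxation modulus is
Fourier-transformed, which is the convention the closed forms above
correspond to. For a solid with a finite equilibrium modulus the
usual convention adds the constant $G_1$ to the storage modulus;
`include_equilibrium_storage = TRUE` provides exactly that, and the
flag defaults to off so that default output matches the closed forms
as stated. The independent route `dynamic_moduli_numeric()` evaluates
the Fourier sine/cosine integrals by adaptive quadrature, truncated
where the decaying part falls below $10^{-12}$ of its initial value
and split at half-periods of the oscillating kernel; it matches the
closed forms to $10^{-3}$ relative (and in practice to $10^{-10}$).
$G''$ peaks at exactly $G_2/2$ at $\omega = G_2/\eta$, a convenient
end-to-end check.

## Units

nN, nm, ms and GPa throughout (1 GPa = 1 nN/nm², so no hidden
constants appear in any contact formula); angular frequency alone is
exposed in rad/s with an explicit ms→s conversion; dynamic moduli are
reported in MPa because that is their natural magnitude for these
materials.

## Parameter extraction

Fitting a relaxation curve recovers $(E_1, E_2, \eta)$ given the
contact configuration and assumed Poisson ratios (a single force
curve cannot identify $\nu$):

* **`fit_three_point()`** mirrors the transient protocol's logic: the
  plateau force fixes $C_r$ and hence the relaxed modulus; the
  initial force fixes $E_1$ through the instantaneous-consistency
  identity; one intermediate point then determines $\eta$ by
  one-dimensional root finding. Three numerical choices matter:
  * *Plateau rule.* $F(\infty)$ is the mean of the final 10% of
    samples (configurable). The flatness requirement — tail drift
    below 1% of the total drop — is applied to the systematic trend
    (difference of consecutive tail-window means) with an allowance
    of 4 standard errors of the point-to-point noise, estimated from
    tail first-differences. A pointwise range test would reject
    almost every realistically noisy curve while adding no
    protection for clean ones; trend testing rejects truncated
    curves just as reliably.
  * *Initial force.* The first samples of a real curve carry contact
    transients, so $F(0)$ is extrapolated from a two-exponential +
    plateau pre-fit (the model family of the solution itself) rather
    than read from the first raw sample.
  * *Intermediate point.* The sample closest to the estimated fast
    relaxation time $1/\hat\alpha$ (log-linear estimate on the early
    transient), where sensitivity to $\eta$ is greatest. A candidate
    already on the plateau is rejected as ill-conditioned.
  The three resulting equations are then polished by a damped
  Gauss--Newton step, so on noiseless model data the generator
  parameters are recovered to machine precision.
* **`fit_least_squares()`** is Levenberg--Marquardt over all points,
  on the log-parameter scale within plausibility bounds ($E$ in
  $(10^{-6}, 10^3)$ GPa, $\eta$ in $(10^{-6}, 10^6)$ GPa·ms — wide
  enough not to constrain any realistic regime), initialized from the
  three-point solve. Parameters landing on a bound are flagged.
* **`fit_dmt_loading()`** extracts the instantaneous sample modulus
  $E_{1s}$ from a loading curve $z = F/k + ((F + 2\pi w
  R)/(E^*\sqrt R))^{2/3}$; the model is linear in $E^{*-2/3}$, so the
  one-parameter least-squares solution is closed-form. The cantilever
  term cancels exactly, and adhesion enters as a known offset — both
  properties are tested.
* **`assemble_sample_properties()`** decouples the cantilever: the
  combined relaxation fit sees cantilever and sample springs in
  series, so $E_{1s}$ replaces $E_1$ while $E_2$ and $\eta$ are kept,
  under the assumption that the cantilever affects only the
  instantaneous response. The implied cantilever series modulus
  $E_{1c} = (1/E_1 - 1/E_{1s})^{-1}$ is reported, but no mapping from
  the spring constant $k$ to a modulus is claimed — that mapping is
  geometry-dependent and not identifiable here. The sample triplet is
  returned in *both* topologies explicitly, because indentation
  predictions consume the series form while uniaxial and dynamic
  predictions conventionally quote the parallel form; making the dual
  reading explicit avoids the ambiguity that shared symbol names
  otherwise invite.

Poisson ratios default to $\nu = 0.3808290$ in the bundled scenario.
This value is *derived*, not measured: it is the unique common
$\nu_1 = \nu_2$ for which the fitted moduli $E_1 = 32.0$ MPa and
$E_2 = 21.3$ MPa give $G_1 + G_2 = 19.3$ MPa, the leading rate
numerator of the fitted relaxation equation; it then independently
reproduces the remaining printed coefficients ($B_r$, $C_r$,
$\beta\eta$) to all four printed decimals, which is strong evidence
it is the value actually used. It is a documented, overridable
default — equal ratios are allowed but never required.

## The synthetic-data generator

`generate_relaxation_curve()` and `generate_loading_curve()` evaluate
the forward models on a grid and add seeded noise
(`noise_spec()`): additive zero-mean Gaussian noise on the measured
axis by default (force for relaxation, displacement for loading),
with a multiplicative option. Additive Gaussian noise is the simplest
defensible instrument model for AFM force detection; nothing finer is
claimed. The default time grid mirrors the transient protocol's delay
times (0, 100, 200, 500, 1000 ms) plus a dense tail to 5000 ms, by
which time the bundled scenario has reached its plateau. With a fixed
seed the output is bit-for-bit reproducible.

What the generator does *not* emulate: approach--retract hysteresis
and snap-in dynamics, thermal drift, contact transients in the first
milliseconds, force-dependent contact-area corrections, or substrate
stiffening (the 10% depth/height QC rule in
`validate_indentation()` is a warning threshold, not a correction).
Passing recovery tests on synthetic curves therefore demonstrates
correctness of the estimator given the model, not robustness to every
instrumental artefact of real curves.

`tmv_scenario()` freezes the bundled study conditions (combined solid
$E_1 = 32.0$ MPa, $E_2 = 21.3$ MPa, $\eta = 12.4$ GPa·ms; $D_0 =
78.457$ nm, $R = 12$ nm, pull-off 16 nN, $k = 5$ nN/nm; sample
$E_{1s} = 2.14$ GPa):

```{r}
sc <- tmv_scenario()
tidy(relaxation_coefficients(sc$solid, sc$contact))
force_relaxation(sc$solid, sc$contact, t = c(0, 1000, 5000))
```

## Problem sizes and test design

The suite exercises each operation on small, fast cases chosen to be
decisive rather than large: identity sweeps use 100 randomized solids
spanning $E \in [10^{-3}, 10]$ GPa and $\eta \in [10^{-1}, 10^3]$
GPa·ms; recovery studies use 100 seeded curves of 50 points each at
2% multiplicative noise (median absolute relative error of each
parameter stays below 5%, least squares within ~2% on $\eta$ and
under 1% on the moduli); oracle-equivalence grids span $t \in [1,
5000]$ ms. The whole suite runs in well under a minute.

## Known limitations

* Single relaxation time: no generalized Maxwell/Prony series, no
  temperature dependence, no nonlinear viscoelasticity.
* DMT adhesion only; soft, strongly adhesive contacts in the JKR
  regime are outside the model's validity.
* Finite sample thickness is only flagged (10% rule), not corrected.
* Poisson ratios are inputs; misspecifying them biases $E_1$, $E_2$
  through the $G$, $K$ conversions (the relaxation *rates* are less
  affected).
* The creep solution assumes an ideal force step; real instruments
  ramp over a finite time.
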