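# afmvisc

Transient viscoelastic analysis of AFM nanoindentation force curves
for soft, adhesive nanomaterials — developed around the tobacco
mosaic virus (TMV)/Ba²⁺ superlattice, a rod-like virus assembly used
as a biotemplate and scaffold candidate whose time-dependent
mechanics matter for tissue engineering. The package is for
experimentalists who acquire force–time relaxation curves (hold the
cantilever end fixed, watch the force decay) and force–displacement
loading curves, and want quantitative elasticity *and* viscosity out
of them instead of frequency-sweep dynamic moduli.

## The model

Adhesive elastic contact in the DMT limit,

$$F + 2\pi w R = \delta^{3/2} E^{*} \sqrt{R}, \qquad
E^{*} = \frac{4E}{3(1-\nu^2)},$$

is extended to a standard linear solid (Zener) material by the
elastic–viscoelastic correspondence method: the elastic constants are
replaced by the material's differential operators, giving a
second-order ODE between force and depth. For a step relative
approach $D_0$ its exact solution is a three-term exponential decay

$$F(t) = \tfrac{4}{3}\sqrt{D_0^{3} R}\,
\big(A_r e^{-\alpha t} + B_r e^{-\beta t} + C_r\big) - 2\pi w R,$$

whose coefficients are closed functions of the shear moduli $G_1,
G_2$, bulk modulus $K_1$ and viscosity $\eta$. The package provides:

* both Zener topologies as first-class types with exact converters;
* the closed-form force relaxation, indentation-depth creep under a
  step force, uniaxial stress relaxation/strain creep, and
  storage/loss shear moduli $G'(\omega)$, $G''(\omega)$;
* independent numerical oracles (Gaver–Stehfest / fixed-Talbot
  inverse Laplace transforms, direct Fourier quadrature) that
  cross-validate every closed form;
* parameter extraction: a three-point solve mirroring the transient
  protocol, damped nonlinear least squares, a one-parameter DMT
  loading fit for the instantaneous modulus, cantilever–sample
  decoupling, pull-off-force→adhesion conversion and indentation
  depth QC;
* a seeded synthetic-curve generator, tidy (`tidy()`/`glance()`/
  `augment()`) accessors, `autoplot()` methods, delimited-text and
  JSON IO, and a CLI (`exec/afmvisc`).

## Worked example

Simulate a noisy relaxation curve under the bundled TMV/Ba²⁺
superlattice study conditions, fit it, and decouple the cantilever:

```r
library(afmvisc)

sc <- tmv_scenario()       # geometry, adhesion, combined solid, E1s
curve <- generate_relaxation_curve(
  sc$solid, sc$contact,
  t_grid = seq(0, 5000, length.out = 50),
  noise  = noise_spec(sd = 2, seed = 42)   # 2 nN additive noise
)
fit <- fit_least_squares(curve, sc$contact, v1 = sc$v)
tidy(fit)
#> # A tibble: 3 × 3
#>   term  estimate units
#>   <chr>    <dbl> <chr>
#> 1 E1      0.0323 GPa
#> 2 E2      0.0207 GPa
#> 3 eta    12.7    GPa ms
glance(fit)$r.squared
#> [1] 0.982
```

The recovered combined parameters sit within a few percent of the
generating values ($E_1 = 0.032$ GPa, $E_2 = 0.0213$ GPa, $\eta =
12.4$ GPa·ms). Adding the loading-curve modulus decouples the
cantilever from the sample:

```r
assemble_sample_properties(fit, E1s = 2.14)
#> <decoupled sample properties>
#>   E1s = 2.14 GPa, E2s = 0.0206809 GPa, eta_s = 12.6607 GPa ms
#>   implied cantilever series modulus E1c = 0.0328281 GPa
```

The coefficient table of the closed-form solution, and the forces it
predicts at the endpoints of the hold:

```r
tidy(relaxation_coefficients(sc$solid, sc$contact))
#> # A tibble: 6 × 3
#>   term        estimate units
#> 1 Ar           0.00696 GPa
#> 2 Br           0.0136  GPa
#> 3 Cr           0.0168  GPa
#> 4 alpha        0.00156 1/ms
#> 5 beta         0.00132 1/ms
#> 6 prefactor 3210.      nm^2
force_relaxation(sc$solid, sc$contact, c(0, 1000))
#> [1] 104.1369  54.48493
```

— an initial force of ~104 nN relaxing towards a ~38 nN plateau,
i.e. ~13.2 nm of tip travel at $k = 5$ nN/nm. The sample's loss
modulus peaks where $\omega = G_{2s}/\eta_s$:

```r
storage_loss_moduli(sc$sample_parallel, c(0.1, 0.622, 10))
#> # A tibble: 3 × 3
#>    omega g_storage_MPa g_loss_MPa
#> 1  0.1           0.194      1.21
#> 2  0.622         3.86       3.86
#> 3 10             7.68       0.478
```

The same pipeline is scriptable from a shell:

```sh
Rscript exec/afmvisc scenario --output cfg.json
Rscript exec/afmvisc simulate relaxation --config cfg.json --sd 2 --seed 7 --output curve.csv
Rscript exec/afmvisc fit-relaxation --input curve.csv --config cfg.json
```

(the `exec/afmvisc` script is also installed with the package and can
be symlinked onto `PATH`).

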