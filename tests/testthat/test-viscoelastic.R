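para <- zener_parallel(E1 = 3, E2 = 0.0213, eta = 12.4, v1 = 0.380829)

test_that("stress relaxation has the standard-solid limits and worked value", {
  expect_equal(stress_relaxation(para, 0.1, 0), 0.1 * (3 + 0.0213))
  expect_equal(stress_relaxation(para, 0.1, 1e9), 0.1 * 3)
  # frozen from direct evaluation at t = 0 with the printed moduli
  expect_equal(stress_relaxation(para, 0.1, 0), 0.30213)
  expect_error(stress_relaxation(para, 0.1, -1), class = "afmvisc_domain_error")
  # strictly decreasing for positive strain
  tgrid <- seq(0, 5000, length.out = 60)
  expect_true(all(diff(stress_relaxation(para, 0.1, tgrid)) < 0))
})

test_that("creep compliance has the reciprocal limits and is non-decreasing", {
  expect_equal(strain_creep(para, 1, 0) * (para$E1 + para$E2), 1, tolerance = 1e-12)
  expect_equal(strain_creep(para, 1, 1e9) * para$E1, 1, tolerance = 1e-12)
  tgrid <- seq(0, 1e4, length.out = 100)
  expect_true(all(diff(strain_creep(para, 0.5, tgrid)) >= 0))
  expect_error(strain_creep(para, 1, -0.1), class = "afmvisc_domain_error")
})

test_that("shear relaxation modulus interpolates G1+G2 -> G1", {
  expect_equal(relaxation_modulus(para, 0), para$G1 + para$G2)
  expect_equal(relaxation_modulus(para, 1e9), para$G1)
  t_star <- para$eta / para$G2 # one relaxation time
  expect_equal(relaxation_modulus(para, t_star), para$G1 + para$G2 / exp(1))
})

test_that("loss modulus peaks at G2/2 at omega = G2/eta", {
  eta_s <- para$eta * 1e-3
  w_star <- para$G2 / eta_s
  peak <- storage_loss_moduli(para, w_star)
  expect_equal(peak$g_loss_MPa, para$G2 / 2 * 1e3, tolerance = 1e-12)
  # grid + golden-section search confirms the analytic maximizer
  opt <- stats::optimize(
    function(w) storage_loss_moduli(para, w)$g_loss_MPa,
    interval = c(1e-3, 1e3), maximum = TRUE, tol = 1e-10
  )
  expect_equal(opt$maximum, w_star, tolerance = 1e-4)
  expect_equal(opt$objective, para$G2 / 2 * 1e3, tolerance = 1e-10)
  # zero frequency: no storage, no loss
  at0 <- storage_loss_moduli(para, 0)
  expect_identical(at0$g_storage_MPa, 0)
  expect_identical(at0$g_loss_MPa, 0)
  expect_error(storage_loss_moduli(para, -1), class = "afmvisc_domain_error")
})

test_that("equilibrium-storage flag adds exactly G1", {
  spec0 <- storage_loss_moduli(para, c(0.1, 1))
  spec1 <- storage_loss_moduli(para, c(0.1, 1), include_equilibrium_storage = TRUE)
  expect_equal(spec1$g_storage_MPa - spec0$g_storage_MPa, rep(para$G1 * 1e3, 2))
  expect_equal(spec1$g_loss_MPa, spec0$g_loss_MPa)
})

test_that("numerical Fourier route matches the closed forms", {
  fn <- function(t_s) relaxation_modulus(para, t_s * 1e3)
  omega <- c(0.01, 0.1, 1, 10, 100)
  num <- dynamic_moduli_numeric(fn, omega)
  cls <- storage_loss_moduli(para, omega)
  expect_equal(num$g_storage_MPa, cls$g_storage_MPa, tolerance = 1e-3)
  expect_equal(num$g_loss_MPa, cls$g_loss_MPa, tolerance = 1e-3)
})

test_that("numerical route is linear and handles degenerate inputs", {
  # sum of two exponentials equals the sum of the single-exponential forms
  g2a <- 0.004; la <- 0.5; g2b <- 0.009; lb = 3
  fn2 <- function(t_s) 0.01 + g2a * exp(-la * t_s) + g2b * exp(-lb * t_s)
  single <- function(g2, lambda, w) {
    # closed-form Fourier integrals of g2*exp(-lambda t)
    c(w^2 * g2 / (lambda^2 + w^2), w * g2 * lambda / (lambda^2 + w^2))
  }
  for (w in c(0.2, 2, 20)) {
    num <- dynamic_moduli_numeric(fn2, w)
    expected <- single(g2a, la, w) + single(g2b, lb, w)
    expect_equal(num$g_storage_MPa, expected[1] * 1e3, tolerance = 1e-6)
    expect_equal(num$g_loss_MPa, expected[2] * 1e3, tolerance = 1e-6)
  }
  # no decaying part: both moduli vanish
  flat <- dynamic_moduli_numeric(function(t_s) rep(0.01, length(t_s)), c(0.5, 5))
  expect_equal(flat$g_storage_MPa, c(0, 0))
  expect_equal(flat$g_loss_MPa, c(0, 0))
  # non-decaying input is refused
  expect_error(
    dynamic_moduli_numeric(function(t_s) 0.01 + 1e-4 * log1p(t_s), 1),
    class = "afmvisc_numerical_error"
  )
})
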