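sc <- tmv_scenario()
tru <- tmv_truth()

rel_err <- function(fit) {
  abs(unlist(fit$estimates, use.names = FALSE) - tru) / tru
}

test_that("three-point fit recovers generator parameters exactly on clean data", {
  curve <- generate_relaxation_curve(sc$solid, sc$contact,
                                     t_grid = seq(0, 5000, length.out = 50))
  fit <- fit_three_point(curve, sc$contact, v1 = sc$v)
  expect_true(all(rel_err(fit) < 1e-6))
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_s3_class(fit$solid, "zener_series")
})

test_that("three-point fit refuses degenerate curves", {
  flat <- afm_curve(seq(0, 5000, length.out = 20), rep(50, 20), "relaxation")
  expect_error(fit_three_point(flat, sc$contact, v1 = sc$v),
               class = "afmvisc_fit_error")
  # truncated curve without a plateau
  short <- generate_relaxation_curve(sc$solid, sc$contact,
                                     t_grid = seq(0, 800, length.out = 30))
  expect_error(fit_three_point(short, sc$contact, v1 = sc$v),
               class = "afmvisc_fit_error", regexp = "plateau")
})

test_that("least squares is exact on clean data and robust to point order", {
  curve <- generate_relaxation_curve(sc$solid, sc$contact,
                                     t_grid = seq(0, 5000, length.out = 50))
  fit <- fit_least_squares(curve, sc$contact, v1 = sc$v)
  expect_true(all(rel_err(fit) < 1e-6))
  expect_equal(fit$r_squared, 1)
  # permuted rows give the identical result
  shuffled <- withr::with_seed(11, tibble::as_tibble(curve)[sample(nrow(curve)), ])
  fit_sh <- fit_least_squares(shuffled, sc$contact, v1 = sc$v)
  expect_equal(unlist(fit_sh$estimates), unlist(fit$estimates), tolerance = 1e-12)
})

test_that("noisy seeded curves are recovered with small bias and high R^2", {
  curve <- generate_relaxation_curve(
    sc$solid, sc$contact, t_grid = seq(0, 5000, length.out = 50),
    noise = noise_spec(sd = 2, seed = 99)
  )
  fit <- fit_least_squares(curve, sc$contact, v1 = sc$v)
  expect_true(all(rel_err(fit) < 0.05))
  expect_gt(fit$r_squared, 0.95)
})

test_that("three-point and least squares agree on noiseless data", {
  curve <- generate_relaxation_curve(sc$solid, sc$contact,
                                     t_grid = seq(0, 5000, length.out = 40))
  f3 <- unlist(fit_three_point(curve, sc$contact, v1 = sc$v)$estimates)
  fl <- unlist(fit_least_squares(curve, sc$contact, v1 = sc$v)$estimates)
  expect_equal(f3, fl, tolerance = 0.01)
})

test_that("parameter recovery sweep: median errors under multiplicative noise stay below 5%", {
  errs <- vapply(1:60, function(i) {
    cv <- generate_relaxation_curve(
      sc$solid, sc$contact, t_grid = seq(0, 5000, length.out = 50),
      noise = noise_spec(sd = 0.02, seed = 5000 + i, model = "multiplicative")
    )
    fit <- tryCatch(fit_least_squares(cv, sc$contact, v1 = sc$v),
                    error = function(e) NULL)
    if (is.null(fit)) rep(NA_real_, 3) else rel_err(fit)
  }, numeric(3))
  expect_true(all(apply(errs, 1, stats::median, na.rm = TRUE) < 0.05))
})

test_that("fits are invariant to uniform time rescaling with eta rescaled", {
  t_ms <- seq(0, 5000, length.out = 40)
  curve_ms <- generate_relaxation_curve(sc$solid, sc$contact, t_grid = t_ms)
  # same curve with the clock read in seconds
  curve_s <- afm_curve(t_ms / 1000, curve_ms$force_nN, "relaxation")
  fit_s <- fit_least_squares(curve_s, sc$contact, v1 = sc$v)
  expect_equal(fit_s$estimates$E1_GPa, tru[["E1"]], tolerance = 1e-6)
  expect_equal(fit_s$estimates$E2_GPa, tru[["E2"]], tolerance = 1e-6)
  expect_equal(fit_s$estimates$eta_GPa_ms, tru[["eta"]] / 1000, tolerance = 1e-6)
})

test_that("DMT loading fit recovers the instantaneous modulus", {
  cc <- sc$contact
  curve <- generate_loading_curve(sc$E1s, sc$v, cc, F_grid = seq(0, 100, 2.5))
  fit <- fit_dmt_loading(curve, cc, v_s = sc$v)
  expect_equal(fit$estimates$E1s_GPa, sc$E1s, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1)
  # adhesion enters as a known offset: doubling w in generation and fit
  # leaves the recovered modulus unchanged
  cc2 <- contact_config(R = 12, k = 5, D0 = 78.457, pull_off = 32)
  curve2 <- generate_loading_curve(sc$E1s, sc$v, cc2, F_grid = seq(0, 100, 2.5))
  fit2 <- fit_dmt_loading(curve2, cc2, v_s = sc$v)
  expect_equal(fit2$estimates$E1s_GPa, fit$estimates$E1s_GPa, tolerance = 1e-10)
  # rigid cantilever curve gives the same modulus (the k term cancels)
  cc_stiff <- contact_config(R = 12, k = 1e12, D0 = 78.457, pull_off = 16)
  curve3 <- generate_loading_curve(sc$E1s, sc$v, cc_stiff, F_grid = seq(0, 100, 2.5))
  fit3 <- fit_dmt_loading(curve3, cc_stiff, v_s = sc$v)
  expect_equal(fit3$estimates$E1s_GPa, fit$estimates$E1s_GPa, tolerance = 1e-8)
  # pre-contact-only data is refused
  bad <- afm_curve(c(-5, -4), c(-20, -18), "loading")
  expect_error(fit_dmt_loading(bad, cc, v_s = sc$v), class = "afmvisc_data_error")
})

test_that("cantilever decoupling assembles the sample parameter set", {
  curve <- generate_relaxation_curve(sc$solid, sc$contact,
                                     t_grid = seq(0, 5000, length.out = 40))
  fit <- fit_least_squares(curve, sc$contact, v1 = sc$v)
  samp <- assemble_sample_properties(fit, E1s = 2.14)
  expect_equal(samp$series$E1, 2.14)
  expect_equal(samp$series$E2, tru[["E2"]], tolerance = 1e-6)
  expect_equal(samp$series$eta, tru[["eta"]], tolerance = 1e-6)
  expect_equal(samp$parallel$E1, 2.14)
  # implied cantilever series modulus from series-spring algebra
  expect_equal(samp$E1c_GPa, 1 / (1 / fit$estimates$E1_GPa - 1 / 2.14),
               tolerance = 1e-12)
  # sample spring softer than the combination is inconsistent
  expect_error(assemble_sample_properties(fit, E1s = 0.01),
               class = "afmvisc_fit_error")
  # equal moduli: degenerate but allowed, with a warning recorded
  samp_eq <- assemble_sample_properties(fit, E1s = fit$estimates$E1_GPa)
  expect_true(is.infinite(samp_eq$E1c_GPa))
  expect_true(any(grepl("degenerate", samp_eq$warnings)))
})

test_that("tidy, glance and augment provide the broom views", {
  curve <- generate_relaxation_curve(sc$solid, sc$contact,
                                     t_grid = seq(0, 5000, length.out = 40))
  fit <- fit_least_squares(curve, sc$contact, v1 = sc$v)
  td <- tidy(fit)
  expect_equal(td$term, c("E1", "E2", "eta"))
  expect_equal(td$units, c("GPa", "GPa", "GPa ms"))
  gl <- glance(fit)
  expect_equal(gl$nobs, 40L)
  expect_equal(gl$method, "least_squares")
  au <- augment(fit)
  expect_true(all(c(".fitted", ".resid") %in% names(au)))
  expect_equal(au$force_nN - au$.fitted, au$.resid)
})
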