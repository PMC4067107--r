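sc <- tmv_scenario()

test_that("contact configuration derives the adhesion offset", {
  cc <- contact_config(R = 12, k = 5, D0 = 78.457, pull_off = 16)
  expect_equal(cc$adhesion_term, 16)
  expect_equal(cc$w, 16 / (2 * pi * 12))
  expect_error(contact_config(R = -1, k = 5, pull_off = 16), class = "afmvisc_domain_error")
  expect_error(contact_config(R = 12, k = 5), class = "afmvisc_domain_error")
  expect_error(contact_config(R = 12, k = 5, w = 0.2, pull_off = 16),
               class = "afmvisc_domain_error")
})

test_that("pull-off conversion follows the DMT and JKR conventions", {
  expect_equal(pull_off_to_adhesion(16, 12, "dmt"), 16 / (2 * pi * 12))
  expect_equal(pull_off_to_adhesion(0, 12), 0)
  # fixed inputs: DMT/JKR ratio is 3/4
  expect_equal(pull_off_to_adhesion(10, 20, "dmt") / pull_off_to_adhesion(10, 20, "jkr"),
               3 / 4)
  expect_error(pull_off_to_adhesion(16, 12, "maugis"))
})

test_that("elastic DMT force and loading displacement are an inverse pair", {
  cc <- contact_config(R = 12, k = 5, pull_off = 16)
  expect_equal(dmt_elastic_force(2.14, 0.380829, cc, 0), -16)
  cc0 <- contact_config(R = 12, k = 5, w = 0)
  expect_equal(dmt_elastic_force(2.14, 0.380829, cc0, 0), 0)
  # frozen closed-form value at delta = 10 nm
  expect_equal(
    dmt_elastic_force(2.14, 0.380829, cc, 10),
    10^1.5 * (4 * 2.14 / (3 * (1 - 0.380829^2))) * sqrt(12) - 16
  )
  expect_error(dmt_elastic_force(2.14, 0.38, cc, -1), class = "afmvisc_domain_error")
  # z at the pull-off force is pure cantilever deflection
  expect_equal(loading_displacement(2.14, 0.38, cc, -16), -16 / 5)
  # rigid cantilever: z reduces to the sample deformation
  cc_stiff <- contact_config(R = 12, k = 1e12, pull_off = 16)
  F <- seq(0, 100, 10)
  z_s <- loading_displacement(2.14, 0.380829, cc_stiff, F)
  expect_equal(dmt_elastic_force(2.14, 0.380829, cc_stiff, z_s), F, tolerance = 1e-8)
  expect_error(loading_displacement(2.14, 0.38, cc, -17), class = "afmvisc_domain_error")
})

test_that("relaxation coefficients reproduce the fitted-equation values", {
  co <- relaxation_coefficients(sc$solid, sc$contact)
  expect_equal(round(co$Ar, 4), 0.0070)
  expect_equal(round(co$Br, 4), 0.0136)
  expect_equal(round(co$Cr, 4), 0.0168)
  expect_equal(round(co$alpha * sc$solid$eta, 4), 0.0193)
  expect_equal(round(co$beta * sc$solid$eta, 4), 0.0163)
  expect_equal(co$prefactor, (4 / 3) * 78.457^1.5 * sqrt(12), tolerance = 1e-12)
  expect_true(co$alpha > co$beta)
})

test_that("force relaxation hits the measured endpoints and decreases monotonically", {
  expect_equal(force_relaxation(sc$solid, sc$contact, 0), 104.21, tolerance = 5e-3)
  expect_equal(force_relaxation(sc$solid, sc$contact, 1e7), 38, tolerance = 5e-3)
  # frozen closed-form value cross-checked against the Laplace oracle
  expect_equal(force_relaxation(sc$solid, sc$contact, 1000), 54.5, tolerance = 1e-3)
  tgrid <- seq(0, 6000, length.out = 200)
  expect_true(all(diff(force_relaxation(sc$solid, sc$contact, tgrid)) < 0))
  expect_error(force_relaxation(sc$solid, sc$contact, -5), class = "afmvisc_domain_error")
  # tip travel between the endpoints
  travel <- (force_relaxation(sc$solid, sc$contact, 0) -
               force_relaxation(sc$solid, sc$contact, 1e7)) / sc$contact$k
  expect_equal(travel, 13.2, tolerance = 5e-3)
})

test_that("instantaneous and relaxed consistency identities hold over random solids", {
  cc <- contact_config(R = 12, k = 5, D0 = 50, pull_off = 16)
  for (s in random_series_solids(100)) {
    if (s$eta == 0) next
    co <- relaxation_coefficients(s, cc)
    expect_equal(co$Ar + co$Br + co$Cr, s$E1 / (1 - s$v1^2), tolerance = 1e-10)
    g_rel <- s$G1 * s$G2 / (s$G1 + s$G2)
    expect_equal(co$Cr, contact_stiffness_from_gk(g_rel, s$K1), tolerance = 1e-10)
    expect_true(co$alpha > co$beta && co$beta > 0)
  }
})

test_that("Laplace oracle agrees with the closed form on the relaxation grid", {
  tgrid <- c(1, 10, 100, 1000, 5000)
  expect_equal(
    laplace_forward_oracle(sc$solid, sc$contact, tgrid),
    force_relaxation(sc$solid, sc$contact, tgrid),
    tolerance = 1e-4
  )
  # near-zero time matches the t = 0 closed form at a relaxed tolerance
  expect_equal(
    laplace_forward_oracle(sc$solid, sc$contact, 1e-3),
    force_relaxation(sc$solid, sc$contact, 0),
    tolerance = 1e-3
  )
  # degenerate dashpot: time-independent relaxed elastic force
  s_el <- zener_series(0.032, 0.0213, 1e-8, v1 = 0.380829)
  co <- relaxation_coefficients(sc$solid, sc$contact)
  f_relaxed <- co$prefactor * co$Cr - sc$contact$adhesion_term
  expect_equal(laplace_forward_oracle(s_el, sc$contact, c(10, 1000)),
               rep(f_relaxed, 2), tolerance = 1e-4)
})

test_that("indentation creep starts at the instantaneous elastic depth and grows", {
  cc <- sc$contact
  cr <- indentation_creep(sc$sample_series, cc, F0 = 50, t = c(0, 1, 10, 100, 1000, 5000))
  # t = 0: elastic DMT depth at the instantaneous moduli
  d0_elastic <- ((50 + cc$adhesion_term) /
                   (4 * sc$E1s / (3 * (1 - sc$v^2)) * sqrt(cc$R)))^(2 / 3)
  expect_equal(cr$depth_nm[1], d0_elastic, tolerance = 1e-10)
  expect_true(all(diff(cr$depth_nm) > 0))
  # larger step force lies above at all times
  cr_hi <- indentation_creep(sc$sample_series, cc, F0 = 80, t = cr$time_ms)
  expect_true(all(cr_hi$depth_nm > cr$depth_nm))
  expect_error(indentation_creep(sc$sample_series, cc, F0 = -20, t = 1),
               class = "afmvisc_domain_error")
})

test_that("creep closed form matches the numerical Laplace oracle", {
  tgrid <- c(1, 5, 20, 100, 500, 2000, 5000)
  cr <- indentation_creep(sc$sample_series, sc$contact, F0 = 50, t = tgrid)
  expect_equal(cr$depth_nm,
               laplace_creep_oracle(sc$sample_series, sc$contact, 50, tgrid),
               tolerance = 1e-3)
  expect_lt(attr(cr, "oracle_check"), 1e-6)
})

test_that("sample-only relaxation reproduces Figure-style sign behavior", {
  # combined solid passed as the sample reduces to the plain solution
  expect_equal(
    force_relaxation_sample_only(sc$solid, sc$contact, c(0, 100, 1000)),
    force_relaxation(sc$solid, sc$contact, c(0, 100, 1000))
  )
  # stiff sample at a small constant depth: relaxes from repulsive to
  # attractive (negative) force
  cc_small <- contact_config(R = 12, k = 5, D0 = 5, pull_off = 16)
  f <- force_relaxation_sample_only(sc$sample_series, cc_small, c(0, 1e7))
  expect_gt(f[1], 0)
  expect_lt(f[2], 0)
  # very soft sample: already on the adhesion side at t = 0, no sign
  # transition during relaxation
  soft <- zener_series(1e-4, 1e-4, 12.4, v1 = 0.380829)
  f_soft <- force_relaxation_sample_only(soft, cc_small, c(0, 1e7))
  expect_true(all(f_soft < 0))
  expect_equal(sign(f_soft[1]), sign(f_soft[2]))
  # parallel-labelled sample triplet is read into the same formulas
  expect_equal(
    force_relaxation_sample_only(sc$sample_parallel, cc_small, c(0, 50)),
    force_relaxation_sample_only(sc$sample_series, cc_small, c(0, 50))
  )
})

test_that("indentation depth QC flags the 10% substrate threshold", {
  expect_false(validate_indentation(13.2, 300)$flagged)
  expect_true(validate_indentation(30, 300)$flagged) # boundary: ratio == 0.10
  expect_false(validate_indentation(5, 1000)$flagged)
  expect_error(validate_indentation(-1, 300), class = "afmvisc_domain_error")
})
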