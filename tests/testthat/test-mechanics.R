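p_ref <- biphasic_params(200, 0.2, 5e-15)
proto_ref <- ramp_hold_protocol(applied_strain = 0.1, ramp_duration = 10,
                                hold_duration = 900, specimen_radius = 1e-3)

test_that("forward model has the right physical limits", {
  # equilibrium: stress -> E * strain
  s_inf <- biphasic_forward(p_ref, proto_ref, 6000)
  expect_equal(s_inf, 200 * 0.1, tolerance = 0.005)

  # free draining (huge permeability): no pressurization, equilibrium
  # response throughout the hold
  p_free <- biphasic_params(200, 0.2, 1e-10)
  t <- c(15, 50, 200, 800)
  expect_equal(biphasic_forward(p_free, proto_ref, t), rep(20, 4),
               tolerance = 0.005)

  # ramp-hold: peak at end of ramp exceeds equilibrium, hold non-increasing
  t <- c(seq(0.5, 10, by = 0.5), seq(11, 900, by = 2))
  s <- biphasic_forward(p_ref, proto_ref, t)
  expect_gt(max(s), 20)
  hold <- s[t >= 10]
  expect_true(all(diff(hold) <= 1e-9))

  expect_error(biphasic_forward(p_ref, proto_ref, c(-1, 5)),
               class = "tissueqc_input_error")
})

test_that("series solution matches the finite-difference oracle within 1%", {
  t <- c(2, 5, 10, 15, 30, 80, 200, 500, 900)
  cases <- expand.grid(E = c(100, 400), nu = c(0.05, 0.35),
                       k = c(1e-15, 2e-14))
  cases <- rbind(cases, data.frame(E = 200, nu = 0.2, k = 5e-15))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    s_series <- biphasic_forward(biphasic_params(cs$E, cs$nu, cs$k),
                                 proto_ref, t)
    s_fd <- fd_biphasic_stress(cs$E, cs$nu, cs$k, 1e-3, 0.1, 10, t)
    expect_lt(max(abs(s_series - s_fd)) / max(s_series), 0.01)
  }
})

test_that("noise-free records are recovered by the fit", {
  rec <- gen_stress_relaxation(p_ref, proto_ref, noise_sd = 0)
  fit <- fit_biphasic(rec, proto_ref)
  expect_true(fit$converged)
  expect_true(fit$plateaued)
  expect_equal(fit$params$youngs_modulus, 200, tolerance = 0.01)
  expect_equal(fit$params$permeability, 5e-15, tolerance = 0.05)
  expect_lt(abs(fit$params$poisson_ratio - 0.2), 0.02)
})

test_that("fixing the Poisson ratio still recovers E and k", {
  rec <- gen_stress_relaxation(p_ref, proto_ref, noise_sd = 0)
  fit <- fit_biphasic(rec, proto_ref, fix_nu = 0.2)
  expect_equal(fit$params$poisson_ratio, 0.2)
  expect_equal(fit$params$youngs_modulus, 200, tolerance = 0.01)
  expect_equal(fit$params$permeability, 5e-15, tolerance = 0.05)
})

test_that("a record truncated before the plateau is flagged", {
  t <- seq(0.5, 60, by = 0.5) # relaxation far from complete at 60 s
  rec <- tibble::tibble(time = t, stress = biphasic_forward(p_ref, proto_ref, t))
  expect_warning(fit <- fit_biphasic(rec, proto_ref),
                 class = "tissueqc_low_confidence")
  expect_false(fit$plateaued)
})

test_that("tensile modulus is the slope of the linear region", {
  strain <- seq(0, 0.12, by = 5e-4)
  lin <- data.frame(strain = strain, stress = 3000 * strain)
  fit <- youngs_modulus_tensile(lin)
  expect_equal(fit$modulus, 3000, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1)

  # quadratic toe then linear region of slope 2000
  toe <- 0.04
  stress <- ifelse(strain < toe, 2000 * strain^2 / (2 * toe),
                   2000 * (strain - toe / 2))
  fit2 <- youngs_modulus_tensile(data.frame(strain = strain, stress = stress))
  expect_equal(fit2$modulus, 2000, tolerance = 0.02)
  expect_gte(fit2$window[1], toe * 0.75) # toe excluded

  withr::with_seed(8, noise <- data.frame(strain = strain,
                                          stress = rnorm(length(strain))))
  expect_error(youngs_modulus_tensile(noise),
               class = "tissueqc_linearity_error")

  # explicit strain range
  fit3 <- youngs_modulus_tensile(data.frame(strain = strain, stress = stress),
                                 region = c(0.08, 0.12))
  expect_equal(fit3$modulus, 2000, tolerance = 1e-6)
  expect_error(youngs_modulus_tensile(lin[1:5, ]),
               class = "tissueqc_input_error")
})

test_that("protocol and parameter constructors validate their domains", {
  expect_error(ramp_hold_protocol(applied_strain = 0.6),
               class = "tissueqc_input_error")
  expect_error(biphasic_params(-5, 0.2, 1e-15), class = "tissueqc_input_error")
  expect_error(biphasic_params(200, 0.5, 1e-15), class = "tissueqc_input_error")
  expect_error(biphasic_params(200, 0.2, 0), class = "tissueqc_input_error")
})
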