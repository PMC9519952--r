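test_that("every generator is a pure function of its spec", {
  fs <- flim_phantom_spec(nx = 16, ny = 16, t_window = 20e-9,
                          noise = "poisson", seed = 5)
  expect_identical(gen_flim_phantom(fs)$decays, gen_flim_phantom(fs)$decays)

  rs <- rf_phantom_spec(extent_um = c(x = 600, y = 600, z = 500),
                        tissue_x = c(100, 500), tissue_z = c(100, 400),
                        seed = 5)
  expect_identical(gen_rf_phantom(rs)$volume$frames,
                   gen_rf_phantom(rs)$volume$frames)

  p <- biphasic_params(150, 0.15, 3e-15)
  proto <- ramp_hold_protocol()
  expect_identical(gen_stress_relaxation(p, proto, noise_sd = 0.02, seed = 3),
                   gen_stress_relaxation(p, proto, noise_sd = 0.02, seed = 3))

  expect_identical(gen_linked_dataset(seed = 9)$samples,
                   gen_linked_dataset(seed = 9)$samples)

  # substreams: different labels from one seed give different streams
  expect_false(substream_seed(1, "flim") == substream_seed(1, "rf"))
})

test_that("FLIm phantoms round-trip through the lifetime pipeline", {
  ph <- gen_flim_phantom(flim_phantom_spec(nx = 24, ny = 24,
                                           base_lifetime = c(ch2 = 4),
                                           t_window = 80e-9, seed = 2))
  maps <- build_lifetime_map(ph$decays)
  got <- map_values(maps$ch2)
  expect_equal(mean(got), 4, tolerance = 0.02)
  # valid pixels are exactly the sample disk
  expect_identical(!is.na(maps$ch2$lifetime), ph$truth$mask)

  # two-patch phantom: homogeneity of the recovered map tracks the truth
  ph2 <- gen_flim_phantom(flim_phantom_spec(
    nx = 32, ny = 32, base_lifetime = c(ch3 = 4),
    patches = list(list(center = c(12, 12), radius = 6, lifetime = 5.2)),
    t_window = 80e-9, seed = 3
  ))
  maps2 <- build_lifetime_map(ph2$decays)
  hf_truth <- flim_homogeneity(ph2$truth$ch3[!is.na(ph2$truth$ch3)])
  hf_map <- flim_homogeneity(maps2$ch3)
  expect_lt(abs(hf_truth - hf_map), 5)
})

test_that("zero-density RF phantoms are pure noise floor", {
  spec <- rf_phantom_spec(extent_um = c(x = 500, y = 400, z = 400),
                          tissue_x = c(100, 400), tissue_z = c(100, 300),
                          scatterer_density = 0, noise_floor = 0.02, seed = 6)
  ph <- gen_rf_phantom(spec)
  rf <- ph$volume$frames
  expect_equal(sd(as.vector(rf)), 0.02, tolerance = 0.02)
  expect_equal(mean(rf), 0, tolerance = 1e-3)
})

test_that("void sizing hits the requested fraction analytically", {
  for (vp in c(2, 5, 12, 20)) {
    spec <- rf_phantom_with_void(vp, seed = 1)
    expect_equal(rf_phantom_truth(spec)$void_percent, vp, tolerance = 1e-10)
  }
  expect_identical(length(rf_phantom_with_void(0)$voids), 0L)
  expect_error(rf_phantom_with_void(25), class = "tissueqc_input_error")
  # voids must stay inside the slab
  expect_error(rf_phantom_spec(voids = list(list(
    center = c(200, 800, 500), semiaxes = c(400, 100, 100),
    density_multiplier = 0
  ))), class = "tissueqc_input_error")
})

test_that("bi-exponential phantoms yield the mixture centroid", {
  ph <- gen_flim_phantom(flim_phantom_spec(
    nx = 12, ny = 12, sample_margin = 1, base_lifetime = c(ch2 = 3),
    tau2 = 8, frac2 = 0.25, t_window = 100e-9, irf_fwhm_ps = 0, seed = 4
  ))
  got <- mean(map_values(build_lifetime_map(ph$decays)$ch2))
  want <- (0.75 * 9 + 0.25 * 64) / (0.75 * 3 + 0.25 * 8)
  expect_equal(got, want, tolerance = 0.02)
})

test_that("noise-free stress records equal the forward model", {
  p <- biphasic_params(220, 0.25, 4e-15)
  proto <- ramp_hold_protocol()
  rec <- gen_stress_relaxation(p, proto, noise_sd = 0)
  expect_equal(rec$stress, biphasic_forward(p, proto, rec$time))
})

test_that("linked datasets embed their generating linear links", {
  links0 <- list(
    collagen = c(intercept = -2, slope = 1.1, sd = 0),
    gag = c(intercept = -1, slope = 2.2, sd = 0),
    compressive = c(intercept = -250, slope = 150, sd = 0),
    tensile = c(intercept = -1500, slope = 800, sd = 0)
  )
  gen <- gen_linked_dataset(n_samples = 20, links = links0, seed = 7)
  m <- fit_linear(gen$samples$ch2_lt, gen$samples$collagen_ww)
  expect_equal(m$slope, 1.1, tolerance = 1e-10)
  expect_equal(m$r_squared, 1)

  # noise set for a population R^2 of 0.7 in a single-group design:
  # R^2 = b^2 var(x) / (b^2 var(x) + sd^2)
  b <- 1.1; sd_lt <- 0.35
  sd_y <- sqrt(b^2 * sd_lt^2 * 0.3 / 0.7)
  gen2 <- gen_linked_dataset(
    n_samples = 200, timepoints = 28, treatments = "CTL",
    treatment_effect = c(CTL = 0), sd_lt = sd_lt,
    links = modifyList(links0, list(collagen = c(intercept = -2, slope = b,
                                                 sd = sd_y))),
    seed = 11
  )
  m2 <- fit_linear(gen2$samples$ch2_lt, gen2$samples$collagen_ww)
  expect_equal(m2$r_squared, 0.7, tolerance = 0.1 / 0.7)
})
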