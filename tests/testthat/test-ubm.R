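fs <- 400e6

test_that("band-pass preserves the passband and rejects out-of-band tones", {
  t <- (0:4095) / fs
  mid <- 1000:3000
  tone42 <- matrix(sin(2 * pi * 42e6 * t), ncol = 1)
  out42 <- bandpass_rf(tone42, fs = fs)
  expect_equal(max(abs(out42[mid, 1])), 1, tolerance = 0.01)

  tone100 <- matrix(sin(2 * pi * 100e6 * t), ncol = 1)
  out100 <- bandpass_rf(tone100, fs = fs)
  atten_db <- 20 * log10(max(abs(out100[mid, 1])))
  expect_lt(atten_db, -40)

  zeros <- matrix(0, 256, 4)
  expect_equal(bandpass_rf(zeros, fs = fs), zeros)

  expect_error(bandpass_rf(tone42, fs = fs, low = 60e6, high = 20e6),
               class = "tissueqc_input_error")
})

test_that("envelope is the analytic-signal magnitude", {
  t <- (0:2047) / fs
  a <- 0.7
  rf <- matrix(a * cos(2 * pi * 42e6 * t), ncol = 1)
  env <- rf_envelope(rf)
  expect_true(all(env >= 0))
  expect_equal(mean(env[500:1500, 1]), a, tolerance = 0.01)

  # Gabor pulse: envelope recovers the Gaussian profile
  sigma <- 40e-9
  g <- exp(-(t - 2.5e-6)^2 / (2 * sigma^2))
  rfg <- matrix(g * cos(2 * pi * 42e6 * t), ncol = 1)
  envg <- rf_envelope(rfg)
  expect_equal(max(envg), 1, tolerance = 0.01)
  expect_lt(max(abs(envg[200:1800, 1] - g[200:1800])), 0.03)

  expect_equal(rf_envelope(matrix(0, 64, 2)), matrix(0, 64, 2))
})

test_that("log compression maps the dynamic range onto 8 bits", {
  env <- matrix(c(1, 10^-1.5, 10^-3, 10^-4), 2, 2)
  img <- log_compress(env, dynamic_range = 60)
  expect_identical(img[1, 1], 255L) # reference -> 255
  expect_identical(img[2, 1], 128L) # -30 dB -> 127.5, rounded half-up
  expect_identical(img[1, 2], 0L)   # -60 dB -> 0
  expect_identical(img[2, 2], 0L)   # below the floor clips to 0

  # monotone non-decreasing in the envelope
  e <- matrix(sort(runif(100)), 10, 10)
  v <- as.vector(log_compress(e))[order(as.vector(e))]
  expect_true(all(diff(v) >= 0))

  expect_error(log_compress(matrix(0, 3, 3)), class = "tissueqc_input_error")
})

test_that("bilinear interpolation is exact on ramps and preserves extent", {
  img <- matrix(5, 8, 10)
  out <- interpolate_bmode(img, native_pixel = c(10, 10), target_pixel = c(5, 5))
  expect_equal(dim(out), c(16, 20))
  expect_true(all(out == 5))

  expect_equal(interpolate_bmode(img, c(5, 5), c(5, 5)), img)

  ramp <- outer(seq(0, 1, length.out = 20), seq(0, 2, length.out = 30), "+")
  up <- interpolate_bmode(ramp, c(10, 10), c(5, 5))
  # affine image: interior of the upsampled image is again an affine ramp
  d1 <- diff(up[5:35, 10])
  expect_equal(max(abs(d1 - d1[1])), 0, tolerance = 1e-10)

  expect_error(interpolate_bmode(ramp, c(10, 10), c(0, 5)),
               class = "tissueqc_input_error")
})

test_that("reconstruction is deterministic and shows Rayleigh speckle", {
  ph <- gen_rf_phantom(rf_phantom_spec(seed = 7))
  # envelope statistics inside the slab: fully developed speckle has
  # SNR = mean/sd = 1.91
  rf <- bandpass_rf(ph$volume$frames[, , 3], fs = ph$volume$fs)
  env <- rf_envelope(rf)
  inside <- env[130:400, 15:50]
  expect_equal(mean(inside) / sd(inside), 1.91, tolerance = 0.08)

  bm1 <- reconstruct_volume(ph$volume)
  bm2 <- reconstruct_volume(ph$volume)
  expect_identical(bm1$frames, bm2$frames)
  expect_equal(bm1$voxel_size, c(5, 5, 200))
  expect_true(all(bm1$frames >= 0L & bm1$frames <= 255L))

  expect_error(reconstruct_volume(rf_volume(array(0, c(64, 4, 2)))),
               class = "tissueqc_input_error")
})

test_that("a scatterer-free void is markedly darker than tissue", {
  ph <- gen_rf_phantom(rf_phantom_with_void(5, seed = 7))
  bm <- reconstruct_volume(ph$volume)
  fr <- bm$frames[, , 5] # void center frame
  v <- ph$spec$voids[[1]]
  rows_v <- round((v$center[3] + c(-0.5, 0.5) * v$semiaxes[3]) / 5)
  cols_v <- round((v$center[1] + c(-0.5, 0.5) * v$semiaxes[1]) / 5)
  void_lvl <- mean(fr[rows_v[1]:rows_v[2], cols_v[1]:cols_v[2]])
  tissue_lvl <- mean(fr[40:70, 40:100])
  expect_gt(tissue_lvl - void_lvl, 20)
})
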