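test_that("background subtraction removes the pre-trigger baseline", {
  w <- subtract_background(c(12, 11, 110, 60, 35), c(1, 2))
  expect_equal(w$samples, c(0.5, -0.5, 98.5, 48.5, 23.5))

  const <- subtract_background(rep(10, 50), 1:10)
  expect_equal(const$samples, rep(0, 50))

  expect_error(subtract_background(1:20, integer(0)),
               class = "tissueqc_input_error")
  expect_error(subtract_background(1:20, c(15, 30)),
               class = "tissueqc_input_error")
})

test_that("average lifetime recovers decay constants", {
  dt <- 80e-12
  t <- (0:1250) * dt # 100 ns window

  # mono-exponential, window = 20 tau
  w <- flim_waveform(exp(-t / 5e-9), dt = dt)
  expect_equal(average_lifetime(w), 5, tolerance = 0.01)

  # two-component decay: centroid = sum(a tau^2) / sum(a tau) = 38/7 ns
  w2 <- flim_waveform(3 * exp(-t / 2e-9) + exp(-t / 8e-9), dt = dt)
  expect_equal(average_lifetime(w2), 38 / 7, tolerance = 0.01)

  # invariance under positive scaling
  expect_identical(average_lifetime(w), average_lifetime(flim_waveform(
    42.7 * exp(-t / 5e-9), dt = dt
  )))

  expect_error(average_lifetime(flim_waveform(rep(0, 100))),
               class = "tissueqc_low_signal")
})

test_that("lifetime maps mark low-signal pixels and recover truth", {
  lt <- matrix(3, 4, 4)
  maps <- build_lifetime_map(make_decay_grid(lt))
  expect_length(maps, 1)
  m <- maps$ch2
  expect_false(anyNA(m$lifetime))
  expect_equal(unname(m$lifetime), matrix(3, 4, 4), tolerance = 0.01)

  lt[2, 3] <- NA # zero-signal pixel
  m2 <- build_lifetime_map(make_decay_grid(lt))$ch2
  expect_identical(which(is.na(m2$lifetime)), which(is.na(lt)))
  expect_equal(sum(is.na(m2$lifetime)), 1L)

  # split phantom: left half 3 ns, right half 6 ns
  lt3 <- cbind(matrix(3, 6, 3), matrix(6, 6, 3))
  m3 <- build_lifetime_map(make_decay_grid(lt3))$ch2
  expect_equal(mean(m3$lifetime[, 1:3]), 3, tolerance = 0.02)
  expect_equal(mean(m3$lifetime[, 4:6]), 6, tolerance = 0.02)

  expect_error(build_lifetime_map(matrix(1, 3, 3)),
               class = "tissueqc_input_error")
})

test_that("ROI statistics use population SD over valid in-circle pixels", {
  m <- lifetime_map(matrix(3, 10, 10))
  st <- roi_statistics(m, center = c(5, 5), radius = 3)
  expect_equal(st$mean_lt, 3)
  expect_equal(st$sd_lt, 0)

  # {2,4} split evenly inside the ROI: mean 3, population sd 1
  vals <- matrix(rep(c(2, 4), each = 50), 10, 10)
  st2 <- roi_statistics(lifetime_map(vals), center = c(5.5, 5.5), radius = 20)
  expect_equal(st2$mean_lt, 3)
  expect_equal(st2$sd_lt, 1)
  expect_equal(st2$n_pixels, 100L)

  # ROI fully outside the valid region
  holey <- matrix(NA_real_, 10, 10); holey[1:3, 1:3] <- 2
  expect_error(roi_statistics(lifetime_map(holey), center = c(9, 9), radius = 1),
               class = "tissueqc_empty_roi")

  # default ROI = largest inscribed circle in the valid region
  st3 <- roi_statistics(lifetime_map(holey))
  expect_gte(st3$n_pixels, 1)
})

test_that("uniform map gives exactly zero ROI spread end to end", {
  maps <- build_lifetime_map(make_decay_grid(matrix(4, 8, 8)))
  st <- roi_statistics(maps$ch2)
  expect_identical(st$sd_lt, 0)
})

test_that("Richardson-Lucy deconvolution recovers the decay shape", {
  dt <- 80e-12
  nt <- 750
  t <- (0:(nt - 1)) * dt
  irf <- exp(-(t - 2e-9)^2 / (2 * (0.4e-9)^2)) # deliberately broad IRF
  decay <- exp(-t / 4e-9)
  observed <- Re(stats::convolve(decay, rev(irf), type = "open"))[seq_len(nt)]
  w <- flim_waveform(observed, dt = dt)
  dec <- deconvolve_irf(w, irf, iterations = 100)
  shape_err <- function(x) {
    x <- x / sum(x)
    sqrt(mean((x - decay / sum(decay))^2))
  }
  expect_lt(shape_err(dec$samples), shape_err(pmax(w$samples, 0)))
})

test_that("spectral bands are the instrument's fixed emission windows", {
  ch <- flim_channels()
  expect_equal(ch$band_low_nm, c(375, 450, 532, 595))
  expect_equal(ch$band_high_nm, c(410, 485, 565, 660))
})
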