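test_that("speckle reduction smooths interiors and preserves edges", {
  const <- matrix(100, 40, 40)
  expect_equal(speckle_reduce(const), const) # diffusion fixed point
  noisy <- matrix(runif(100, 50, 150), 10, 10)
  expect_identical(speckle_reduce(noisy, iterations = 0), noisy)

  # textured two-level phantom: interior variance halves, boundary gradient
  # magnitude keeps at least half of its pre-filter value
  fr <- make_bmode_frame(texture_sd = 18, seed = 42)$img
  sm <- speckle_reduce(fr)
  inner <- function(m) m[40:120, 40:200]
  expect_lt(var(as.vector(inner(sm))), 0.5 * var(as.vector(inner(fr))))

  grad_row <- function(m, r) mean(abs(m[r + 1, 30:210] - m[r - 1, 30:210]) / 2)
  edge <- round(160 * 0.15) # top tissue boundary of the phantom
  expect_gt(grad_row(sm, edge), 0.5 * grad_row(fr, edge))

  expect_error(speckle_reduce(fr, iterations = -1),
               class = "tissueqc_input_error")
})

test_that("median fallback smooths too", {
  fr <- make_bmode_frame(texture_sd = 18, seed = 43)$img
  sm <- speckle_reduce(fr, method = "median")
  expect_lt(var(as.vector(sm[40:120, 40:200])),
            var(as.vector(fr[40:120, 40:200])))
})

test_that("total segmentation matches the bimodal ground truth exactly", {
  img <- matrix(20, 80, 120)
  img[21:60, 31:90] <- 200 # noise-free two-mode frame
  mask <- segment_total(img)
  truth <- matrix(FALSE, 80, 120); truth[21:60, 31:90] <- TRUE
  expect_identical(mask, truth)

  # interior dark hole is flood-filled into the total mask
  img2 <- img
  img2[35:45, 55:70] <- 15
  expect_identical(segment_total(img2), truth)

  expect_warning(m0 <- segment_total(matrix(0, 20, 20)),
                 class = "tissueqc_empty_mask")
  expect_false(any(m0))
})

test_that("package Otsu agrees with a brute-force threshold search", {
  withr::with_seed(5, {
    x <- c(rnorm(4000, 0.2, 0.05), rnorm(2000, 0.7, 0.08))
    img <- matrix(pmin(pmax(x, 0), 1), 60, 100)
  })
  th_pkg <- EBImage::otsu(EBImage::Image(img), range = c(0, 1), levels = 256L)
  th_brute <- brute_otsu(img, levels = 256)
  # both thresholds must separate the two modes and induce near-identical
  # masks (the implementations differ in bin/midpoint conventions)
  expect_true(th_pkg > 0.25 && th_pkg < 0.65)
  expect_true(th_brute > 0.25 && th_brute < 0.65)
  expect_gt(mean((img > th_pkg) == (img > th_brute)), 0.99)
})

test_that("void segmentation finds dark regions inside the sample", {
  r <- 22
  ph <- make_bmode_frame(voids = list(list(center = c(80, 120), radius = r)),
                         seed = 9)
  sm <- speckle_reduce(ph$img)
  total <- segment_total(sm)
  voids <- segment_voids(sm, total)
  expect_equal(sum(voids), pi * r^2, tolerance = 0.15)

  # dark area outside the total mask is excluded by construction
  expect_true(all(total[voids]))

  # no-void phantoms: false positives below 0.5% of the total mask
  fp <- vapply(1:20, function(s) {
    ph0 <- make_bmode_frame(seed = 100 + s)
    sm0 <- speckle_reduce(ph0$img)
    t0 <- segment_total(sm0)
    sum(segment_voids(sm0, t0)) / sum(t0)
  }, numeric(1))
  expect_lt(max(fp), 0.005)

  expect_error(segment_voids(sm, total[1:10, 1:10]),
               class = "tissueqc_input_error")
})

test_that("mask interpolation reproduces originals and interpolates shapes", {
  disk <- function(r, n = 64) {
    rows <- matrix(seq_len(n), n, n); cols <- t(rows)
    (rows - n / 2)^2 + (cols - n / 2)^2 <= r^2
  }
  same <- simplify2array(list(disk(12), disk(12)))
  out <- interpolate_masks(same, 5)
  expect_equal(dim(out)[3], 6L) # (n-1)*factor + 1
  for (k in 1:6) expect_identical(out[, , k], disk(12))

  grow <- simplify2array(list(disk(10), disk(20)))
  mid <- interpolate_masks(grow, 2)[, , 2]
  r_mid <- sqrt(sum(mid) / pi)
  expect_equal(r_mid, 15, tolerance = 1 / 15)

  expect_identical(interpolate_masks(grow, 1), grow)
  expect_error(interpolate_masks(disk(5), 4), class = "tissueqc_input_error")
  expect_error(interpolate_masks(grow, 0), class = "tissueqc_input_error")
})

test_that("void percentage is voxel counting times voxel volume", {
  vox <- array(FALSE, c(20, 25, 20)) # 10000 voxels
  vox[1:20, 1:25, 1:20] <- TRUE
  void <- array(FALSE, c(20, 25, 20))
  void[1:5, 1:10, 1:10] <- TRUE # 500 voxels
  vs <- c(5, 5, 10)
  res <- void_volume_percent(mask_volume(vox, vs, "total"),
                             mask_volume(void, vs, "void"))
  expect_equal(res$void_percent, 5)
  expect_equal(res$total_mm3, 10000 * 250 * 1e-9)

  res0 <- void_volume_percent(mask_volume(vox, vs, "total"),
                              mask_volume(array(FALSE, dim(vox)), vs, "void"))
  expect_equal(res0$void_percent, 0)

  expect_error(
    void_volume_percent(mask_volume(array(FALSE, dim(vox)), vs, "total"),
                        mask_volume(void, vs, "void")),
    class = "tissueqc_undefined_result"
  )
})

test_that("estimated void volume never decreases when the true void grows", {
  scales <- c(0.6, 1, 1.4)
  ests <- vapply(scales, function(s) {
    spec <- rf_phantom_spec(
      voids = list(list(center = c(800, 800, 500),
                        semiaxes = c(220, 420, 150) * s,
                        density_multiplier = 0)),
      seed = 12
    )
    bm <- reconstruct_volume(gen_rf_phantom(spec)$volume)
    void_volumetry(bm)$void_percent
  }, numeric(1))
  expect_true(all(diff(ests) >= 0))
})
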