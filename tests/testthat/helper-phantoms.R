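# Small in-code fixtures shared by the tests.

# decay array [ny, nx, 1, nt] with a per-pixel lifetime matrix (ns);
# NA pixels carry zero signal
make_decay_grid <- function(lt, dt = 80e-12, t_window = 60e-9, peak = 1000) {
  nt <- round(t_window / dt)
  t <- (seq_len(nt) - 1) * dt
  t0 <- 0.1 * t_window
  arr <- array(0, c(nrow(lt), ncol(lt), 1, nt))
  for (i in seq_len(nrow(lt))) {
    for (j in seq_len(ncol(lt))) {
      if (!is.na(lt[i, j])) {
        arr[i, j, 1, ] <- peak * ifelse(t >= t0, exp(-(t - t0) / (lt[i, j] * 1e-9)), 0)
      }
    }
  }
  attr(arr, "dt") <- dt
  attr(arr, "channels") <- 2L
  arr
}

# synthetic speckle-reduced-looking B-mode frame on the 8-bit log scale:
# tissue rectangle around `tissue_level` with mild texture, background near
# zero, optional dark circular voids; edges smoothed
make_bmode_frame <- function(nr = 160, nc = 240, tissue_level = 200,
                             bg_level = 12, texture_sd = 5,
                             voids = list(), void_level = 10, seed = 1) {
  withr::with_seed(seed, {
    img <- matrix(bg_level + rnorm(nr * nc, 0, 2), nr, nc)
    tr <- round(nr * c(0.15, 0.85)); tc <- round(nc * c(0.1, 0.9))
    tissue <- matrix(FALSE, nr, nc)
    tissue[tr[1]:tr[2], tc[1]:tc[2]] <- TRUE
    img[tissue] <- tissue_level + rnorm(sum(tissue), 0, texture_sd)
    for (v in voids) {
      rows <- matrix(seq_len(nr), nr, nc)
      cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
      inside <- (rows - v$center[1])^2 + (cols - v$center[2])^2 <= v$radius^2
      img[inside] <- void_level + rnorm(sum(inside), 0, 1)
    }
    img <- EBImage::imageData(EBImage::gblur(EBImage::Image(img / 255), 1.5)) * 255
    list(img = pmin(pmax(img, 0), 255), tissue = tissue)
  })
}
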