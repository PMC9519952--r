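#' Spectral detection bands of the fluorescence-lifetime imager
#'
#' The instrument separates autofluorescence into four fixed emission bands.
#' Channel 2 (450–485 nm) reports collagen-associated fluorescence and channel
#' 3 (532–565 nm) reports metabolic/matrix fluorophores; these two carry the
#' biochemical information used downstream.
#'
#' @return A tibble with one row per channel: `channel`, `band_low_nm`,
#'   `band_high_nm`.
#' @export
#' @examples
#' flim_channels()
flim_channels <- function() {
  tibble(
    channel = 1:4,
    band_low_nm = c(375, 450, 532, 595),
    band_high_nm = c(410, 485, 565, 660)
  )
}

#' Construct a fluorescence decay waveform
#'
#' A decay waveform is the time-resolved fluorescence intensity recorded at one
#' pixel in one spectral band, sampled at the digitizer resolution (80 ps by
#' default).
#'
#' @param samples Numeric vector of intensities (arbitrary units), length >= 2.
#' @param dt Sampling interval in seconds (default 80 ps).
#' @param channel Spectral channel, integer 1–4.
#' @return An object of class `flim_waveform`.
#' @export
flim_waveform <- function(samples, dt = 80e-12, channel = 2L) {
  if (!is.numeric(samples) || length(samples) < 2L) {
    stop_input("`samples` must be a numeric vector of length >= 2.")
  }
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  if (!channel %in% 1:4) stop_input("`channel` must be an integer in 1..4.")
  structure(
    list(samples = as.numeric(samples), dt = dt, channel = as.integer(channel)),
    class = "flim_waveform"
  )
}

#' @export
print.flim_waveform <- function(x, ...) {
  cat(sprintf(
    "<flim_waveform> CH%d, %d samples @ %.0f ps (window %.1f ns)\n",
    x$channel, length(x$samples), x$dt * 1e12, length(x$samples) * x$dt * 1e9
  ))
  invisible(x)
}

as_waveform <- function(w, dt = 80e-12, channel = 2L) {
  if (inherits(w, "flim_waveform")) w else flim_waveform(w, dt = dt, channel = channel)
}

#' Subtract the pre-trigger background from a decay waveform
#'
#' Estimates the baseline as the mean over a pre-onset sample window and
#' subtracts it. Values may become negative (noise); they are clipped to zero
#' only when intensities are summed by [average_lifetime()].
#'
#' @param w A [flim_waveform()] or numeric vector.
#' @param pre_window Integer indices of samples lying before the decay onset,
#'   either a full index vector or a length-2 `c(first, last)` range.
#' @inheritParams flim_waveform
#' @return A `flim_waveform` with the baseline removed.
#' @export
subtract_background <- function(w, pre_window, dt = 80e-12, channel = 2L) {
  w <- as_waveform(w, dt, channel)
  n <- length(w$samples)
  if (length(pre_window) == 2L && pre_window[2] > pre_window[1] + 1) {
    pre_window <- seq.int(pre_window[1], pre_window[2])
  }
  pre_window <- as.integer(pre_window)
  if (length(pre_window) == 0L || anyNA(pre_window) ||
      any(pre_window < 1L) || any(pre_window > n)) {
    stop_input("`pre_window` must be a non-empty set of in-bounds sample indices.")
  }
  w$samples <- w$samples - mean(w$samples[pre_window])
  w
}

moving_average3 <- function(x) {
  n <- length(x)
  xm <- c(x[1], x[-n])
  xp <- c(x[-1], x[n])
  (xm + x + xp) / 3
}

#' Intensity-weighted average fluorescence lifetime of a decay
#'
#' Computes the temporal centroid of the background-subtracted decay measured
#' from the decay onset: \eqn{\sum_k (t_k - t_{onset}) I_k / \sum_k I_k}, plus
#' a half-sample (+dt/2) correction that treats samples as bin centers. For a
#' mono-exponential decay observed over a window much longer than the lifetime
#' this equals the decay constant \eqn{\tau}.
#'
#' Negative post-subtraction samples are clipped to zero before summation; the
#' onset is the argmax of a 3-sample moving average (`onset = "peak"`) or the
#' first sample exceeding `threshold` times the smoothed maximum
#' (`onset = "threshold"`).
#'
#' @inheritParams subtract_background
#' @param onset Onset policy, `"peak"` or `"threshold"`.
#' @param threshold Fraction of the smoothed peak used by the threshold policy.
#' @param min_signal Minimum total post-clip intensity for a valid pixel;
#'   decays below it raise a low-signal error (condition class
#'   `tissueqc_low_signal`).
#' @return Average lifetime in nanoseconds.
#' @export
#' @examples
#' t <- (0:1250) * 80e-12
#' w <- flim_waveform(exp(-t / 5e-9))
#' average_lifetime(w) # ~= 5 ns
average_lifetime <- function(w, onset = c("peak", "threshold"), threshold = 0.1,
                             min_signal = 0, dt = 80e-12, channel = 2L) {
  w <- as_waveform(w, dt, channel)
  onset <- match.arg(onset)
  x <- pmax(w$samples, 0)
  total <- sum(x)
  if (total <= 0 || total < min_signal) {
    abort("Total intensity too low for a stable lifetime estimate.",
          class = "tissueqc_low_signal")
  }
  s <- moving_average3(x)
  i0 <- if (onset == "peak") {
    which.max(s)
  } else {
    idx <- which(s >= threshold * max(s))
    idx[1]
  }
  k <- seq_along(x) - i0
  keep <- k >= 0
  tail_total <- sum(x[keep])
  if (tail_total <= 0) {
    abort("No intensity at or after the decay onset.",
          class = "tissueqc_low_signal")
  }
  centroid <- sum(k[keep] * x[keep]) / tail_total
  (centroid + 0.5) * w$dt * 1e9
}

#' Richardson–Lucy deconvolution of an instrument response
#'
#' Optional preprocessing for decays measurably broadened by the instrument
#' response function (IRF). Iterative Richardson–Lucy deconvolution of the
#' (non-negative) waveform by a user-supplied IRF waveform.
#'
#' @inheritParams subtract_background
#' @param irf Numeric vector, the measured instrument response (same dt).
#' @param iterations Number of multiplicative updates.
#' @return A `flim_waveform` holding the deconvolved decay.
#' @export
deconvolve_irf <- function(w, irf, iterations = 25, dt = 80e-12, channel = 2L) {
  w <- as_waveform(w, dt, channel)
  if (!is.numeric(irf) || length(irf) < 1L || all(irf <= 0)) {
    stop_input("`irf` must be a numeric vector with positive mass.")
  }
  check_number(iterations, "iterations", lower = 1)
  y <- pmax(w$samples, 0)
  n <- length(y)
  h <- irf / sum(irf)
  # linear convolution via zero-padded FFT
  m <- stats::nextn(n + length(h) - 1L, 2)
  H <- stats::fft(c(h, rep(0, m - length(h))))
  conv_h <- function(v) {
    Re(stats::fft(stats::fft(c(v, rep(0, m - n))) * H, inverse = TRUE) / m)[seq_len(n)]
  }
  Hc <- Conj(H)
  corr_h <- function(v) {
    Re(stats::fft(stats::fft(c(v, rep(0, m - n))) * Hc, inverse = TRUE) / m)[seq_len(n)]
  }
  est <- pmax(y, 1e-12)
  for (i in seq_len(iterations)) {
    pred <- pmax(conv_h(est), 1e-12)
    est <- est * pmax(corr_h(y / pred), 0)
  }
  w$samples <- est
  w
}

#' Build per-channel average-lifetime maps from a raster decay scan
#'
#' Converts a rectangular grid of per-pixel decay waveforms into one lifetime
#' map per spectral channel. Pixels whose total post-clip intensity falls below
#' the low-signal threshold carry `NA`; the co-registered intensity plane holds
#' the per-pixel total intensity.
#'
#' @param decays Numeric array `[ny, nx, nch, nt]` (or `[ny, nx, nt]` for a
#'   single channel) of decay samples. The per-channel slices must share `dt`.
#' @param dt Sampling interval in seconds; taken from `attr(decays, "dt")`
#'   when present.
#' @param pixel_pitch Pixel pitch in micrometres (default 20).
#' @param channels Integer channel ids matching the third dimension; defaults
#'   to `attr(decays, "channels")` or `seq_len(nch)`.
#' @param pre_window Sample indices used for background subtraction; defaults
#'   to the first 5% of the record (at least 4 samples).
#' @param min_signal_factor Low-signal threshold expressed as a multiple of the
#'   per-sample background standard deviation (default 50). The background SD
#'   is estimated per pixel from `pre_window` after baseline removal.
#' @param onset,threshold Passed to [average_lifetime()].
#' @return A named list of `lifetime_map` objects, one per channel. Each holds
#'   `lifetime` (matrix, ns, `NA` = missing), `intensity`, `pixel_pitch`,
#'   `channel`.
#' @export
build_lifetime_map <- function(decays, dt = NULL, pixel_pitch = 20,
                               channels = NULL, pre_window = NULL,
                               min_signal_factor = 50,
                               onset = c("peak", "threshold"), threshold = 0.1) {
  onset <- match.arg(onset)
  if (is.null(dt)) dt <- attr(decays, "dt")
  if (is.null(dt)) dt <- 80e-12
  if (!is.array(decays) || !length(dim(decays)) %in% c(3L, 4L)) {
    stop_input("`decays` must be a [ny, nx, nch, nt] or [ny, nx, nt] array.")
  }
  if (length(dim(decays)) == 3L) {
    dim(decays) <- c(dim(decays)[1:2], 1L, dim(decays)[3])
  }
  dms <- dim(decays)
  ny <- dms[1]; nx <- dms[2]; nch <- dms[3]; nt <- dms[4]
  if (nt < 2L) stop_input("Decay records must have at least 2 samples.")
  if (is.null(channels)) channels <- attr(decays, "channels")
  if (is.null(channels)) channels <- seq_len(nch)
  if (length(channels) != nch) stop_input("`channels` length must match dim 3.")
  if (is.null(pre_window)) pre_window <- seq_len(max(4L, floor(0.05 * nt)))
  pre_window <- as.integer(pre_window)
  if (any(pre_window < 1L) || any(pre_window > nt)) {
    stop_input("`pre_window` out of bounds.")
  }

  maps <- lapply(seq_len(nch), function(ci) {
    m <- matrix(aperm(decays[, , ci, , drop = FALSE], c(1, 2, 4, 3)),
                nrow = ny * nx, ncol = nt)
    bg <- rowMeans(m[, pre_window, drop = FALSE])
    m <- m - bg
    bg_sd <- apply(m[, pre_window, drop = FALSE], 1, sd)
    m[m < 0] <- 0
    total <- rowSums(m)
    min_signal <- min_signal_factor * bg_sd
    valid <- total > 0 & total >= min_signal

    # smoothed argmax onset, vectorised over pixels
    sm <- (m[, c(1, seq_len(nt - 1)), drop = FALSE] + m +
             m[, c(seq_len(nt - 1) + 1, nt), drop = FALSE]) / 3
    i0 <- if (onset == "peak") {
      max.col(sm, ties.method = "first")
    } else {
      apply(sm, 1, function(r) which(r >= threshold * max(r))[1])
    }

    lt <- rep(NA_real_, ny * nx)
    idx <- which(valid)
    if (length(idx)) {
      lt[idx] <- vapply(idx, function(i) {
        k <- seq_len(nt) - i0[i]
        keep <- k >= 0
        tt <- sum(m[i, keep])
        if (tt <= 0) return(NA_real_)
        (sum(k[keep] * m[i, keep]) / tt + 0.5) * dt * 1e9
      }, numeric(1))
    }
    new_lifetime_map(matrix(lt, ny, nx), matrix(total, ny, nx),
                     pixel_pitch, channels[ci])
  })
  names(maps) <- paste0("ch", channels)
  maps
}

new_lifetime_map <- function(lifetime, intensity, pixel_pitch, channel) {
  stopifnot(identical(dim(lifetime), dim(intensity)))
  structure(
    list(lifetime = lifetime, intensity = intensity,
         pixel_pitch = pixel_pitch, channel = as.integer(channel)),
    class = "lifetime_map"
  )
}

#' Create a lifetime map from a matrix of lifetimes
#'
#' Mostly useful for tests and for re-reading maps from disk.
#'
#' @param lifetime Matrix of lifetimes in ns (`NA` = missing pixel).
#' @param intensity Optional co-registered total-intensity matrix.
#' @param pixel_pitch Pixel pitch, µm.
#' @param channel Spectral channel id.
#' @return A `lifetime_map`.
#' @export
lifetime_map <- function(lifetime, intensity = NULL, pixel_pitch = 20,
                         channel = 2L) {
  if (!is.matrix(lifetime)) stop_input("`lifetime` must be a matrix.")
  if (any(lifetime[is.finite(lifetime)] <= 0)) {
    stop_input("All finite lifetimes must be > 0 ns.")
  }
  if (is.null(intensity)) intensity <- (!is.na(lifetime)) * 1
  new_lifetime_map(lifetime, intensity, pixel_pitch, channel)
}

#' @export
print.lifetime_map <- function(x, ...) {
  v <- x$lifetime[!is.na(x$lifetime)]
  cat(sprintf(
    "<lifetime_map> CH%d %dx%d px @ %g um | %d valid px, mean %.2f ns\n",
    x$channel, nrow(x$lifetime), ncol(x$lifetime), x$pixel_pitch,
    length(v), if (length(v)) mean(v) else NA_real_
  ))
  invisible(x)
}

#' Valid lifetime values of a map
#'
#' @param map A `lifetime_map`.
#' @return Numeric vector of non-missing lifetimes (ns).
#' @export
map_values <- function(map) {
  stopifnot(inherits(map, "lifetime_map"))
  as.numeric(map$lifetime[!is.na(map$lifetime)])
}

#' Largest circular region of interest inscribed in the valid pixel region
#'
#' @param map A `lifetime_map`.
#' @return List with `center` (row, col) and `radius` in pixels.
#' @export
largest_inscribed_roi <- function(map) {
  stopifnot(inherits(map, "lifetime_map"))
  valid <- !is.na(map$lifetime)
  if (!any(valid)) abort("Map has no valid pixels.", class = "tissueqc_empty_roi")
  d <- EBImage::imageData(EBImage::distmap(EBImage::Image(valid * 1)))
  d[!is.finite(d)] <- min(dim(valid)) # fully valid map: distance to the edge
  i <- which.max(d)
  rc <- arrayInd(i, dim(d))
  r_max <- (min(dim(valid)) - 1) / 2
  list(center = c(rc[1], rc[2]), radius = min(max(d[i] - 1, 1), r_max))
}

#' Mean and standard deviation of lifetime over a circular ROI
#'
#' Statistics are computed over non-missing pixels whose centers fall within
#' the circle. The standard deviation is the population SD (divide by n): the
#' ROI pixels are the full population of interest, not a sample from it.
#'
#' @param map A `lifetime_map`.
#' @param center ROI center as `c(row, col)` in pixels; default: center of the
#'   largest circle inscribed in the valid region.
#' @param radius ROI radius in pixels; default: radius of that circle.
#' @return A one-row tibble: `channel`, `mean_lt`, `sd_lt`, `n_pixels`,
#'   `center_row`, `center_col`, `radius`.
#' @export
roi_statistics <- function(map, center = NULL, radius = NULL) {
  stopifnot(inherits(map, "lifetime_map"))
  if (is.null(center) || is.null(radius)) {
    roi <- largest_inscribed_roi(map)
    if (is.null(center)) center <- roi$center
    if (is.null(radius)) radius <- roi$radius
  }
  check_number(radius, "radius", lower = 0, strict_lower = TRUE)
  nr <- nrow(map$lifetime); nc <- ncol(map$lifetime)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  inside <- (rows - center[1])^2 + (cols - center[2])^2 <= radius^2
  vals <- map$lifetime[inside & !is.na(map$lifetime)]
  if (length(vals) == 0L) {
    abort("ROI contains no valid pixels.", class = "tissueqc_empty_roi")
  }
  n <- length(vals)
  tibble(
    channel = map$channel,
    mean_lt = mean(vals),
    sd_lt = sqrt(sum((vals - mean(vals))^2) / n),
    n_pixels = n,
    center_row = center[1], center_col = center[2], radius = radius
  )
}
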