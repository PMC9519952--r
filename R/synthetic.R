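#' Specification of a synthetic FLIm phantom
#'
#' Describes a raster scan of a disk-shaped sample surrounded by a zero-signal
#' background, with optional circular patches of altered lifetime. Decays are
#' mono-exponential (optionally bi-exponential) convolved with a Gaussian
#' instrument response, sampled at the digitizer resolution.
#'
#' @param nx,ny Grid size in pixels.
#' @param pixel_pitch Pixel pitch, µm.
#' @param base_lifetime Named numeric vector of per-channel lifetimes in ns,
#'   names `"ch2"`, `"ch3"`, ... (channels to simulate).
#' @param patches List of patches, each
#'   `list(center = c(row, col), radius = px, lifetime = ns)` where `lifetime`
#'   is a single value or a named per-channel vector.
#' @param sample_margin Background margin around the sample disk, px.
#' @param peak_counts Peak intensity of the brightest decay, counts.
#' @param background_counts Constant baseline added to every sample (counts).
#' @param noise `"none"`, `"poisson"` or `"gaussian"`.
#' @param noise_sd Absolute SD of Gaussian noise (counts); ignored otherwise.
#' @param irf_fwhm_ps Full width at half maximum of the Gaussian IRF, ps
#'   (0 = ideal impulse).
#' @param dt Sampling interval, s.
#' @param t_window Total record length, s.
#' @param tau2,frac2 Optional second decay component (lifetime ns and its
#'   amplitude fraction) shared by all pixels, for estimator-bias studies.
#' @param seed Integer seed.
#' @return A list of class `flim_phantom_spec`.
#' @export
flim_phantom_spec <- function(nx = 48, ny = 48, pixel_pitch = 20,
                              base_lifetime = c(ch2 = 4.5, ch3 = 4.0),
                              patches = list(), sample_margin = 4,
                              peak_counts = 1000, background_counts = 0,
                              noise = c("none", "poisson", "gaussian"),
                              noise_sd = 0, irf_fwhm_ps = 100,
                              dt = 80e-12, t_window = 60e-9,
                              tau2 = NULL, frac2 = 0, seed = 1) {
  noise <- match.arg(noise)
  if (any(base_lifetime <= 0)) stop_input("Lifetimes must be > 0 ns.")
  if (peak_counts <= 0) stop_input("`peak_counts` must be > 0.")
  if (min(nx, ny) / 2 - sample_margin < 1) {
    stop_input("Grid too small for `sample_margin`: the sample disk is empty.")
  }
  structure(
    list(nx = nx, ny = ny, pixel_pitch = pixel_pitch,
         base_lifetime = base_lifetime, patches = patches,
         sample_margin = sample_margin, peak_counts = peak_counts,
         background_counts = background_counts, noise = noise,
         noise_sd = noise_sd, irf_fwhm_ps = irf_fwhm_ps, dt = dt,
         t_window = t_window, tau2 = tau2, frac2 = frac2, seed = seed),
    class = "flim_phantom_spec"
  )
}

# exponential decay (lifetime tau_ns) convolved with a Gaussian IRF,
# evaluated on t (s); exact exponentially-modified-Gaussian expression
decay_curve <- function(t, t0, tau_ns, sigma_s) {
  tau <- tau_ns * 1e-9
  if (sigma_s <= 0) {
    return(ifelse(t >= t0, exp(-(t - t0) / tau), 0))
  }
  erfc <- function(z) 2 * pnorm(-z * sqrt(2))
  arg <- (sigma_s^2 / tau - (t - t0)) / (sqrt(2) * sigma_s)
  0.5 * exp(sigma_s^2 / (2 * tau^2) - (t - t0) / tau) * erfc(arg)
}

#' Generate a synthetic FLIm decay scan with known ground truth
#'
#' Builds the per-pixel decay array in the layout expected by
#' [build_lifetime_map()] (`[ny, nx, nch, nt]` with attributes `dt` and
#' `channels`) together with the true lifetime image per channel. The
#' generator is a pure function of its spec: identical specs (seed included)
#' give bit-identical output.
#'
#' @param spec A [flim_phantom_spec()].
#' @return List with `decays` (array), `truth` (per-channel true lifetime
#'   matrices, `NA` outside the sample, plus the sample `mask`), and `spec`.
#' @export
gen_flim_phantom <- function(spec) {
  stopifnot(inherits(spec, "flim_phantom_spec"))
  withr::with_seed(substream_seed(spec$seed, "flim"), {
    nt <- as.integer(round(spec$t_window / spec$dt))
    t <- (seq_len(nt) - 1) * spec$dt
    t0 <- 0.1 * spec$t_window # decay onset well after the pre-trigger window
    sigma_s <- spec$irf_fwhm_ps * 1e-12 / (2 * sqrt(2 * log(2)))

    channels <- as.integer(sub("ch", "", names(spec$base_lifetime)))
    nch <- length(channels)

    cx <- (spec$ny + 1) / 2; cy <- (spec$nx + 1) / 2
    rad <- min(spec$nx, spec$ny) / 2 - spec$sample_margin
    rows <- matrix(seq_len(spec$ny), spec$ny, spec$nx)
    cols <- matrix(seq_len(spec$nx), spec$ny, spec$nx, byrow = TRUE)
    mask <- (rows - cx)^2 + (cols - cy)^2 <= rad^2

    truth <- list(mask = mask)
    decays <- array(0, c(spec$ny, spec$nx, nch, nt))
    for (ci in seq_len(nch)) {
      ch_name <- names(spec$base_lifetime)[ci]
      lt <- matrix(NA_real_, spec$ny, spec$nx)
      lt[mask] <- spec$base_lifetime[[ci]]
      for (p in spec$patches) {
        plt <- if (length(p$lifetime) > 1) p$lifetime[[ch_name]] else p$lifetime
        if (is.null(plt) || is.na(plt)) next
        inside <- (rows - p$center[1])^2 + (cols - p$center[2])^2 <= p$radius^2
        lt[inside & mask] <- plt
      }
      truth[[ch_name]] <- lt

      for (tau in unique(lt[!is.na(lt)])) {
        curve <- decay_curve(t, t0, tau, sigma_s)
        if (!is.null(spec$tau2) && spec$frac2 > 0) {
          curve <- (1 - spec$frac2) * curve +
            spec$frac2 * decay_curve(t, t0, spec$tau2, sigma_s)
        }
        curve <- curve / max(curve) * spec$peak_counts
        idx <- which(!is.na(lt) & lt == tau)
        for (i in idx) {
          r <- ((i - 1) %% spec$ny) + 1
          cc <- ((i - 1) %/% spec$ny) + 1
          decays[r, cc, ci, ] <- curve
        }
      }
    }
    decays <- decays + spec$background_counts
    if (spec$noise == "poisson") {
      decays[] <- rpois(length(decays), pmax(decays, 0))
    } else if (spec$noise == "gaussian" && spec$noise_sd > 0) {
      decays[] <- decays + rnorm(length(decays), 0, spec$noise_sd)
    }
    attr(decays, "dt") <- spec$dt
    attr(decays, "channels") <- channels
    list(decays = decays, truth = truth, spec = spec)
  })
}

#' Specification of a synthetic RF speckle phantom
#'
#' A rectangular tissue slab filled with randomly placed sub-resolution
#' scatterers (fully developed speckle at the default density), containing
#' optional scatterer-free ellipsoidal voids, scanned as parallel frames of
#' A-lines. Axes: x lateral (scan lines), y elevation (frames), z depth
#' (axial).
#'
#' @param extent_um Named numeric `c(x=, y=, z=)`: scanned volume, µm.
#' @param tissue_x,tissue_z Length-2 ranges (µm) of the slab in x and z; the
#'   slab spans the full y extent.
#' @param scatterer_density Scatterers per mm^3; the default keeps >= 10
#'   scatterers per resolution cell (fully developed speckle).
#' @param amplitude `"gaussian"` (zero-mean, Rayleigh envelope) or
#'   `"rayleigh"` scatterer amplitudes.
#' @param voids List of `list(center = c(x, y, z), semiaxes = c(ax, ay, az),
#'   density_multiplier = 0)` in µm.
#' @param pulse_freq Pulse center frequency, Hz.
#' @param fractional_bandwidth Gaussian pulse fractional bandwidth.
#' @param fs Sampling rate, Hz.
#' @param line_pitch Lateral A-line spacing, µm.
#' @param frame_spacing Elevational frame spacing, µm.
#' @param beam_sigma Lateral beam Gaussian sigma, µm.
#' @param elev_sigma Elevational (slice-thickness) Gaussian sigma, µm. The
#'   defaults match the focal beam of an f/1.5 high-frequency transducer
#'   (4 mm aperture, 6 mm focus) at 42 MHz, whose diffraction-limited focal
#'   width is about 55 µm FWHM.
#' @param noise_floor SD of additive Gaussian RF noise, relative to unit
#'   scatterer amplitude.
#' @param sound_speed Speed of sound, m/s.
#' @param seed Integer seed.
#' @return A list of class `rf_phantom_spec`.
#' @export
rf_phantom_spec <- function(extent_um = c(x = 1600, y = 1600, z = 1000),
                            tissue_x = c(150, 1450), tissue_z = c(150, 850),
                            scatterer_density = 60000,
                            amplitude = c("gaussian", "rayleigh"),
                            voids = list(),
                            pulse_freq = 42e6, fractional_bandwidth = 0.4,
                            fs = 400e6, line_pitch = 25, frame_spacing = 200,
                            beam_sigma = 30, elev_sigma = 30,
                            noise_floor = 0.02, sound_speed = 1540, seed = 1) {
  amplitude <- match.arg(amplitude)
  if (scatterer_density < 0) stop_input("`scatterer_density` must be >= 0.")
  for (v in voids) {
    lo <- v$center - v$semiaxes
    hi <- v$center + v$semiaxes
    if (lo[1] < tissue_x[1] || hi[1] > tissue_x[2] ||
        lo[3] < tissue_z[1] || hi[3] > tissue_z[2] ||
        lo[2] < 0 || hi[2] > extent_um[["y"]]) {
      stop_input("Voids must lie within the tissue slab and scanned extent.")
    }
  }
  structure(
    list(extent_um = extent_um, tissue_x = tissue_x, tissue_z = tissue_z,
         scatterer_density = scatterer_density, amplitude = amplitude,
         voids = voids, pulse_freq = pulse_freq,
         fractional_bandwidth = fractional_bandwidth, fs = fs,
         line_pitch = line_pitch, frame_spacing = frame_spacing,
         beam_sigma = beam_sigma, elev_sigma = elev_sigma,
         noise_floor = noise_floor, sound_speed = sound_speed, seed = seed),
    class = "rf_phantom_spec"
  )
}

#' RF phantom spec with voids totalling a prescribed void fraction
#'
#' Sizes ellipsoidal voids so that their combined volume is `void_percent` %
#' of the tissue-slab volume. Up to about 5% a single centered void is used
#' (a sphere when it fits within the slab thickness, otherwise an oblate
#' ellipsoid); larger fractions are split over two cleft-like voids elongated
#' along the elevation axis at mid-depth, mirroring the elongated matrix
#' clefts seen in poorly matured constructs. Every void keeps a generous
#' tissue ring to the slab faces (thin blurred tissue bands would otherwise
#' merge a void with the background in the reconstructed images, as they
#' would in a real scan).
#'
#' @param void_percent Target total void volume, percent of the slab volume
#'   (0 gives a void-free phantom; capped at 20).
#' @param max_semi_z Largest allowed depth semi-axis, µm.
#' @param max_single_percent Largest void fraction placed as a single void.
#' @param ... Passed to [rf_phantom_spec()].
#' @return A `rf_phantom_spec`.
#' @export
rf_phantom_with_void <- function(void_percent, max_semi_z = 220,
                                 max_single_percent = 5.1, ...) {
  spec <- rf_phantom_spec(...)
  if (void_percent < 0 || void_percent > 20) {
    stop_input("`void_percent` must be in [0, 20].")
  }
  if (void_percent == 0) return(spec)
  slab <- c(diff(spec$tissue_x), spec$extent_um[["y"]], diff(spec$tissue_z))
  z_mid <- mean(spec$tissue_z)

  if (void_percent <= max_single_percent) {
    v_one <- void_percent / 100 * prod(slab)
    az1 <- min(max_semi_z, 190)
    r_sphere <- (3 * v_one / (4 * pi))^(1 / 3)
    semi <- if (r_sphere <= az1) {
      rep(r_sphere, 3)
    } else {
      c(rep(sqrt(3 * v_one / (4 * pi * az1)), 2), az1)
    }
    centers <- list(c(mean(spec$tissue_x), spec$extent_um[["y"]] / 2, z_mid))
  } else {
    # one cleft elongated along the elevation axis at mid-depth, widening
    # laterally with the target fraction
    v_one <- void_percent / 100 * prod(slab)
    ay <- spec$extent_um[["y"]] / 2 - 100
    az <- min(max_semi_z, 220)
    ax <- 3 * v_one / (4 * pi * ay * az)
    semi <- c(ax, ay, az)
    centers <- list(c(mean(spec$tissue_x), spec$extent_um[["y"]] / 2, z_mid))
  }
  spec$voids <- lapply(centers, function(ctr) {
    list(center = ctr, semiaxes = semi, density_multiplier = 0)
  })
  # re-validate geometry
  do.call(rf_phantom_spec, c(
    list(extent_um = spec$extent_um, tissue_x = spec$tissue_x,
         tissue_z = spec$tissue_z, voids = spec$voids),
    spec[c("scatterer_density", "amplitude", "pulse_freq",
           "fractional_bandwidth", "fs", "line_pitch", "frame_spacing",
           "beam_sigma", "elev_sigma", "noise_floor", "sound_speed", "seed")]
  ))
}

#' True void fraction of an RF phantom spec
#'
#' Analytic ellipsoid volume over slab volume, in percent.
#'
#' @param spec A `rf_phantom_spec`.
#' @return List with `total_mm3`, `void_mm3`, `void_percent`.
#' @export
rf_phantom_truth <- function(spec) {
  stopifnot(inherits(spec, "rf_phantom_spec"))
  slab_um3 <- diff(spec$tissue_x) * spec$extent_um[["y"]] * diff(spec$tissue_z)
  void_um3 <- sum(vapply(spec$voids, function(v) {
    (1 - min(max(v$density_multiplier, 0), 1)) * 4 / 3 * pi * prod(v$semiaxes)
  }, numeric(1)))
  list(total_mm3 = slab_um3 * 1e-9, void_mm3 = void_um3 * 1e-9,
       void_percent = 100 * void_um3 / slab_um3)
}

gabor_pulse <- function(fs, f0, fbw, n_sigma = 4) {
  sigma_f <- fbw * f0 / (2 * sqrt(2 * log(2)))
  sigma_t <- 1 / (2 * pi * sigma_f)
  half <- ceiling(n_sigma * sigma_t * fs)
  t <- (-half:half) / fs
  exp(-t^2 / (2 * sigma_t^2)) * cos(2 * pi * f0 * t)
}

#' Generate a synthetic RF volume with known void ground truth
#'
#' Scatterers are placed by a seeded uniform point process over the tissue
#' slab, thinned inside voids according to their density multiplier, weighted
#' by Gaussian elevation (slice thickness) and lateral beam profiles, binned
#' onto the A-line sample grid, convolved axially with a Gabor pulse at the
#' transducer center frequency, and overlaid with Gaussian receiver noise.
#' The placement draws do not depend on the void list, so enlarging a void
#' (same seed) only removes scatterers.
#'
#' @param spec An [rf_phantom_spec()].
#' @return List with `volume` (an [rf_volume()]), `truth`
#'   (see [rf_phantom_truth()]), and `spec`.
#' @export
gen_rf_phantom <- function(spec) {
  stopifnot(inherits(spec, "rf_phantom_spec"))
  withr::with_seed(substream_seed(spec$seed, "rf"), {
    ex <- spec$extent_um
    slab_vol_mm3 <- diff(spec$tissue_x) * ex[["y"]] * diff(spec$tissue_z) * 1e-9
    n_scat <- as.integer(round(spec$scatterer_density * slab_vol_mm3))
    sx <- runif(n_scat, spec$tissue_x[1], spec$tissue_x[2])
    sy <- runif(n_scat, 0, ex[["y"]])
    sz <- runif(n_scat, spec$tissue_z[1], spec$tissue_z[2])
    amp <- if (spec$amplitude == "gaussian") {
      rnorm(n_scat)
    } else {
      sqrt(rnorm(n_scat)^2 + rnorm(n_scat)^2)
    }
    thin <- runif(n_scat)
    keep <- rep(TRUE, n_scat)
    for (v in spec$voids) {
      d2 <- ((sx - v$center[1]) / v$semiaxes[1])^2 +
        ((sy - v$center[2]) / v$semiaxes[2])^2 +
        ((sz - v$center[3]) / v$semiaxes[3])^2
      m <- min(max(v$density_multiplier, 0), 1)
      keep <- keep & !(d2 <= 1 & thin >= m)
    }
    sx <- sx[keep]; sy <- sy[keep]; sz <- sz[keep]; amp <- amp[keep]

    n_lines <- as.integer(round(ex[["x"]] / spec$line_pitch))
    n_frames <- as.integer(floor(ex[["y"]] / spec$frame_spacing)) + 1L
    n_samp <- as.integer(ceiling(2 * ex[["z"]] * 1e-6 / spec$sound_speed *
                                   spec$fs)) + 8L
    pulse <- gabor_pulse(spec$fs, spec$pulse_freq, spec$fractional_bandwidth)
    half <- (length(pulse) - 1L) / 2L
    nfft <- stats::nextn(n_samp + length(pulse), 2)
    P <- stats::fft(c(pulse, rep(0, nfft - length(pulse))))

    # axial sample of each scatterer (round-trip time of flight)
    si <- as.integer(round(2 * sz * 1e-6 / spec$sound_speed * spec$fs)) + 1L
    line_centers <- (seq_len(n_lines) - 0.5) * spec$line_pitch
    frames <- array(0, c(n_samp, n_lines, n_frames))
    off_max <- max(1L, ceiling(2.5 * spec$beam_sigma / spec$line_pitch))

    for (f in seq_len(n_frames)) {
      yf <- (f - 1) * spec$frame_spacing
      sel <- which(abs(sy - yf) < 3 * spec$elev_sigma)
      img <- matrix(0, n_samp, n_lines)
      if (length(sel)) {
        w_e <- exp(-(sy[sel] - yf)^2 / (2 * spec$elev_sigma^2)) * amp[sel]
        l0 <- sx[sel] / spec$line_pitch + 0.5 # fractional line index
        for (off in -off_max:off_max) {
          li <- as.integer(round(l0)) + off
          ok <- li >= 1L & li <= n_lines & si[sel] >= 1L & si[sel] <= n_samp
          if (!any(ok)) next
          w <- w_e[ok] * exp(-((line_centers[li[ok]] - sx[sel][ok])^2) /
                               (2 * spec$beam_sigma^2))
          acc <- Matrix::sparseMatrix(
            i = si[sel][ok], j = li[ok], x = w, dims = c(n_samp, n_lines)
          )
          img <- img + as.matrix(acc)
        }
        X <- stats::mvfft(rbind(img, matrix(0, nfft - n_samp, n_lines)))
        conv <- Re(stats::mvfft(X * P, inverse = TRUE) / nfft)
        img <- conv[(half + 1):(half + n_samp), , drop = FALSE]
      }
      if (spec$noise_floor > 0) {
        img <- img + matrix(rnorm(n_samp * n_lines, 0, spec$noise_floor),
                            n_samp, n_lines)
      }
      frames[, , f] <- img
    }
    vol <- rf_volume(frames, fs = spec$fs, line_pitch = spec$line_pitch,
                     frame_spacing = spec$frame_spacing)
    list(volume = vol, truth = rf_phantom_truth(spec), spec = spec)
  })
}

#' Generate a synthetic stress-relaxation record
#'
#' Evaluates the biphasic forward model on a uniform time grid over the
#' ramp-hold protocol and applies multiplicative Gaussian noise.
#'
#' @param p A [biphasic_params()].
#' @param proto A [ramp_hold_protocol()].
#' @param noise_sd Multiplicative noise SD (e.g. 0.02 for 2%).
#' @param dt Sampling interval of the record, s.
#' @param seed Integer seed.
#' @param n_roots Series terms of the forward model.
#' @return A tibble with `time` (s) and `stress` (kPa).
#' @export
gen_stress_relaxation <- function(p, proto, noise_sd = 0, dt = 0.5, seed = 1,
                                  n_roots = 50) {
  stopifnot(inherits(p, "biphasic_params"), inherits(proto, "ramp_hold_protocol"))
  time <- seq(0, proto$ramp_duration + proto$hold_duration, by = dt)[-1]
  stress <- biphasic_forward(p, proto, time, n_roots)
  if (noise_sd > 0) {
    withr::with_seed(substream_seed(seed, "mech"), {
      stress <- stress * (1 + rnorm(length(stress), 0, noise_sd))
    })
  }
  tibble(time = time, stress = stress)
}

#' Generate a linked optical/destructive dataset with known ground truth
#'
#' Emulates a longitudinal study in which every construct is imaged
#' non-destructively (per-channel mean lifetimes) and assayed destructively
#' (biochemistry and mechanics). Lifetimes drift upward with culture day and
#' differ slightly by treatment; each destructive value is generated through a
#' linear link from its lifetime predictor plus Gaussian noise.
#'
#' Default links: collagen (% wet weight) from CH2 lifetime, GAG (% wet
#' weight) and compressive modulus (kPa) from CH3 lifetime, tensile modulus
#' (kPa) from CH2 lifetime.
#'
#' @param n_samples Number of constructs (each observed at all timepoints).
#' @param timepoints Culture days of observation.
#' @param treatments Treatment labels cycled over constructs.
#' @param base_lt Named `c(ch2=, ch3=)` baseline lifetimes at the first
#'   timepoint, ns.
#' @param day_slope Lifetime drift per day, ns.
#' @param treatment_effect Named per-treatment lifetime offset, ns.
#' @param sd_lt Within-group lifetime SD, ns.
#' @param links Named list of linear links, each
#'   `c(intercept =, slope =, sd =)`, names `collagen`, `gag`, `compressive`,
#'   `tensile`.
#' @param seed Integer seed.
#' @return List with `samples` (tibble: `sample_id`, `treatment`, `day`,
#'   `ch2_lt`, `ch3_lt`, `collagen_ww`, `gag_ww`, `compressive_modulus`,
#'   `tensile_modulus`) and `truth` (the generating links and settings).
#' @export
gen_linked_dataset <- function(n_samples = 48,
                               timepoints = c(7, 14, 21, 28),
                               treatments = c("CTL", "TGF", "LAP"),
                               base_lt = c(ch2 = 3.9, ch3 = 3.3),
                               day_slope = 0.04,
                               treatment_effect = c(CTL = 0, TGF = 0.10, LAP = 0.15),
                               sd_lt = 0.35,
                               links = list(
                                 collagen = c(intercept = -2.0, slope = 1.1, sd = 0.42),
                                 gag = c(intercept = -1.0, slope = 2.2, sd = 0.9),
                                 compressive = c(intercept = -250, slope = 150, sd = 60),
                                 tensile = c(intercept = -1500, slope = 800, sd = 350)
                               ),
                               seed = 1) {
  if (n_samples < 3) stop_input("`n_samples` must be >= 3.")
  if (any(vapply(links, function(l) l[["sd"]], numeric(1)) < 0)) {
    stop_input("Link noise SDs must be >= 0.")
  }
  withr::with_seed(substream_seed(seed, "linked"), {
    grid <- expand.grid(sample_id = seq_len(n_samples), day = timepoints,
                        KEEP.OUT.ATTRS = FALSE)
    trt <- treatments[(grid$sample_id - 1) %% length(treatments) + 1]
    te <- unname(treatment_effect[trt])
    te[is.na(te)] <- 0
    n <- nrow(grid)
    drift <- day_slope * (grid$day - min(timepoints))
    ch2 <- base_lt[["ch2"]] + drift + te + rnorm(n, 0, sd_lt)
    ch3 <- base_lt[["ch3"]] + drift + te + rnorm(n, 0, sd_lt)
    gen_link <- function(l, x) l[["intercept"]] + l[["slope"]] * x +
      rnorm(n, 0, l[["sd"]])
    samples <- tibble(
      sample_id = sprintf("S%02d", grid$sample_id),
      treatment = trt,
      day = grid$day,
      ch2_lt = ch2,
      ch3_lt = ch3,
      collagen_ww = gen_link(links$collagen, ch2),
      gag_ww = gen_link(links$gag, ch3),
      compressive_modulus = gen_link(links$compressive, ch3),
      tensile_modulus = gen_link(links$tensile, ch2)
    )
    list(samples = samples,
         truth = list(links = links, base_lt = base_lt, day_slope = day_slope,
                      treatment_effect = treatment_effect, sd_lt = sd_lt))
  })
}
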