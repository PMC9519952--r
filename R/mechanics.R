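#' Ramp–hold protocol of an unconfined stress-relaxation test
#'
#' Geometry and loading of the compressive test: a cylindrical specimen is
#' compressed between impermeable, frictionless platens to `applied_strain`
#' over `ramp_duration`, then held while the stress relaxes as interstitial
#' fluid exudes radially.
#'
#' @param applied_strain Axial engineering strain (0–0.5, typically 0.1).
#' @param ramp_duration Ramp time, s.
#' @param hold_duration Hold time, s.
#' @param specimen_radius Specimen radius, m.
#' @param specimen_height Specimen height, m.
#' @return An object of class `ramp_hold_protocol`.
#' @export
ramp_hold_protocol <- function(applied_strain = 0.1, ramp_duration = 10,
                               hold_duration = 900, specimen_radius = 1e-3,
                               specimen_height = 1e-3) {
  check_number(applied_strain, "applied_strain", lower = 0, upper = 0.5,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(ramp_duration, "ramp_duration", lower = 0, strict_lower = TRUE)
  check_number(hold_duration, "hold_duration", lower = 0, strict_lower = TRUE)
  check_number(specimen_radius, "specimen_radius", lower = 0, strict_lower = TRUE)
  check_number(specimen_height, "specimen_height", lower = 0, strict_lower = TRUE)
  structure(
    list(applied_strain = applied_strain, ramp_duration = ramp_duration,
         hold_duration = hold_duration, specimen_radius = specimen_radius,
         specimen_height = specimen_height),
    class = "ramp_hold_protocol"
  )
}

#' Biphasic material parameters
#'
#' Parameters of the linear biphasic (porous-elastic) model of cartilage: the
#' drained Young's modulus of the solid matrix, its Poisson ratio, and the
#' hydraulic permeability governing fluid exudation.
#'
#' @param youngs_modulus Young's modulus E, kPa (> 0).
#' @param poisson_ratio Poisson ratio of the solid matrix, in `[0, 0.5)`.
#' @param permeability Hydraulic permeability k, m^4/(N s) (> 0).
#' @return An object of class `biphasic_params`.
#' @export
biphasic_params <- function(youngs_modulus, poisson_ratio, permeability) {
  check_number(youngs_modulus, "youngs_modulus", lower = 0, strict_lower = TRUE)
  check_number(poisson_ratio, "poisson_ratio", lower = 0, upper = 0.5,
               strict_upper = TRUE)
  check_number(permeability, "permeability", lower = 0, strict_lower = TRUE)
  structure(
    list(youngs_modulus = youngs_modulus, poisson_ratio = poisson_ratio,
         permeability = permeability),
    class = "biphasic_params"
  )
}

#' @export
print.biphasic_params <- function(x, ...) {
  cat(sprintf("<biphasic_params> E = %.3g kPa, nu = %.3f, k = %.3g m^4/(N s)\n",
              x$youngs_modulus, x$poisson_ratio, x$permeability))
  invisible(x)
}

.tissueqc_cache <- new.env(parent = emptyenv())

# zeros of J0 (independent of material parameters), cached per session
bessel_j0_zeros <- function(n) {
  have <- .tissueqc_cache$j0
  if (!is.null(have) && length(have) >= n) return(have[seq_len(n)])
  j0 <- vapply(seq_len(n), function(k) {
    uniroot(function(x) besselJ(x, 0),
            c((k - 0.75) * pi, (k - 0.25) * pi + 0.3), tol = 1e-13)$root
  }, numeric(1))
  .tissueqc_cache$j0 <- j0
  j0
}

# roots of the characteristic equation J1(a) = beta * a * J0(a),
# beta = (1 - nu)/(1 - 2 nu); one root per interval between zeros of J0
biphasic_roots <- function(nu, n_roots = 50) {
  beta <- (1 - nu) / (1 - 2 * nu)
  f <- function(a) besselJ(a, 1) - beta * a * besselJ(a, 0)
  j0 <- bessel_j0_zeros(n_roots)
  lo <- c(1e-8, j0[-n_roots] + 1e-9)
  hi <- j0 - 1e-9
  vapply(seq_len(n_roots), function(n) {
    uniroot(f, c(lo[n], hi[n]), tol = 1e-13)$root
  }, numeric(1))
}

biphasic_modes <- function(p, proto, n_roots = 50) {
  E <- p$youngs_modulus            # kPa
  nu <- p$poisson_ratio
  k <- p$permeability              # m^4/(N s)
  mu <- E / (2 * (1 + nu))         # kPa
  HA <- E * (1 - nu) / ((1 + nu) * (1 - 2 * nu)) # kPa
  beta <- (1 - nu) / (1 - 2 * nu)
  a <- proto$specimen_radius
  tau_g <- a^2 / (HA * 1e3 * k)    # gel diffusion time, s (HA in Pa)
  alpha <- biphasic_roots(nu, n_roots)
  list(
    E = E, mu = mu, HA = HA,
    lambda_n = alpha^2 / tau_g,
    c_n = 2 * mu * beta / (beta^2 * alpha^2 + 1 - 2 * beta) # kPa
  )
}

#' Axial stress history of a biphasic disk in unconfined ramp–hold compression
#'
#' Series solution of the linear biphasic boundary-value problem for a
#' cylindrical disk compressed between frictionless impermeable platens with
#' free radial draining: the relaxation spectrum is set by the roots
#' \eqn{\alpha_n} of \eqn{J_1(\alpha) = \beta \alpha J_0(\alpha)} with
#' \eqn{\beta = (1-\nu)/(1-2\nu)}, decay rates \eqn{\alpha_n^2 H_A k / a^2},
#' and mode amplitudes \eqn{2\mu\beta / (\beta^2\alpha_n^2 + 1 - 2\beta)}.
#' Ramp loading is handled by exact superposition (Duhamel convolution of the
#' step response with the constant ramp rate). As \eqn{t \to \infty} the
#' stress approaches the equilibrium value \eqn{E \epsilon_0}.
#'
#' @param p A [biphasic_params()].
#' @param proto A [ramp_hold_protocol()].
#' @param time Numeric vector of times, s (from test start).
#' @param n_roots Number of series terms (default 50).
#' @return Engineering stress in kPa at `time` (compression positive).
#' @export
biphasic_forward <- function(p, proto, time, n_roots = 50) {
  stopifnot(inherits(p, "biphasic_params"), inherits(proto, "ramp_hold_protocol"))
  if (!is.numeric(time) || any(time < 0)) {
    stop_input("`time` must be non-negative.")
  }
  m <- biphasic_modes(p, proto, n_roots)
  if (any(!is.finite(m$lambda_n)) || any(!is.finite(m$c_n))) {
    abort("Biphasic series did not converge for these parameters.",
          class = "tissueqc_numeric_error")
  }
  # tail check on the ramp-response amplitudes c_n / lambda_n (~ n^-4)
  amp <- m$c_n / m$lambda_n
  if (amp[n_roots] > 1e-5 * max(amp)) {
    warn("Biphasic series truncation may be coarse; increase `n_roots`.")
  }
  tr <- proto$ramp_duration
  rate <- proto$applied_strain / tr
  tm <- pmin(time, tr)
  sapply_terms <- outer(m$lambda_n, time) # [n_roots x nt], lambda * t
  decay_all <- exp(-sapply_terms)
  decay_since_ramp <- exp(-m$lambda_n %o% (time - tm))
  series <- colSums((m$c_n / m$lambda_n) * (decay_since_ramp - decay_all))
  rate * (m$E * tm + series)
}

# heuristic start values from the record shape
biphasic_start <- function(time, stress, proto) {
  eps <- proto$applied_strain
  n <- length(stress)
  plateau <- mean(stress[time >= max(time) * 0.95])
  E0 <- max(plateau / eps, 1e-3)
  peak <- max(stress)
  i_pk <- which.max(stress)
  # time for the relaxing part to fall to 1/e of (peak - plateau)
  target <- plateau + (peak - plateau) / exp(1)
  after <- which(seq_len(n) > i_pk & stress <= target)
  t63 <- if (length(after)) time[after[1]] - time[i_pk] else max(time) / 5
  list(E0 = E0, t63 = max(t63, 1e-3))
}

theta_pack <- function(E, nu, k) {
  c(log(E), stats::qlogis(nu / 0.5), log(k))
}
theta_unpack <- function(th) {
  list(E = exp(th[1]), nu = 0.5 * stats::plogis(th[2]), k = exp(th[3]))
}

#' Fit biphasic parameters to an unconfined stress-relaxation record
#'
#' Nonlinear least squares of [biphasic_forward()] to a measured
#' stress–time record. Parameters are log-transformed (E, k) and
#' logit-transformed (nu) to enforce their physical bounds; optimization uses
#' Levenberg–Marquardt with a fixed design of deterministic multi-starts.
#'
#' If the record does not reach its relaxation plateau (final stress more than
#' 5% of the relaxation amplitude away from flat), the fit is flagged
#' low-confidence.
#'
#' @param data A data frame with columns `time` (s) and `stress` (kPa), e.g.
#'   from [gen_stress_relaxation()].
#' @param proto A [ramp_hold_protocol()].
#' @param init Optional [biphasic_params()] start; used as the first start.
#' @param fix_nu Optional fixed Poisson ratio; when given only E and k are
#'   fitted.
#' @param n_roots Series terms for the forward model.
#' @return An object of class `biphasic_fit`: fitted [biphasic_params()] in
#'   `params`, plus `residual_norm`, `converged`, `plateaued`, `n_starts`,
#'   and the data/fitted values. Supports [tidy()], [glance()], `autoplot()`.
#' @export
fit_biphasic <- function(data, proto, init = NULL, fix_nu = NULL, n_roots = 50) {
  stopifnot(inherits(proto, "ramp_hold_protocol"))
  data <- as.data.frame(data)
  if (!all(c("time", "stress") %in% names(data))) {
    stop_input("`data` must have columns `time` and `stress`.")
  }
  time <- data$time
  stress <- data$stress
  if (is.unsorted(time, strictly = TRUE)) {
    stop_input("`time` must be strictly increasing.")
  }
  s <- biphasic_start(time, stress, proto)
  # plateau check: drift over the last decile relative to relaxation amplitude
  last <- time >= max(time) * 0.9
  amp <- max(stress) - stress[length(stress)]
  drift <- abs(mean(stress[last][seq_len(ceiling(sum(last) / 2))]) -
                 stress[length(stress)])
  plateaued <- amp <= 0 || drift <= 0.05 * max(amp, 1e-12)
  if (!plateaued) {
    warn("Record does not reach its relaxation plateau; fit flagged low-confidence.",
         class = "tissueqc_low_confidence")
  }

  a <- proto$specimen_radius
  starts <- list(
    list(nu = 0.05, km = 1), list(nu = 0.20, km = 1), list(nu = 0.35, km = 1),
    list(nu = 0.20, km = 0.2), list(nu = 0.20, km = 5)
  )
  k_from <- function(nu) {
    HA <- s$E0 * (1 - nu) / ((1 + nu) * (1 - 2 * nu)) * 1e3
    a1 <- biphasic_roots(nu, 1)[1]
    a^2 / (HA * a1^2 * s$t63)
  }

  resid_fun <- function(th) {
    pp <- if (is.null(fix_nu)) {
      theta_unpack(th)
    } else {
      list(E = exp(th[1]), nu = fix_nu, k = exp(th[2]))
    }
    p <- biphasic_params(pp$E, pp$nu, pp$k)
    biphasic_forward(p, proto, time, n_roots) - stress
  }

  best <- NULL
  start_list <- lapply(starts, function(st) {
    if (is.null(fix_nu)) {
      theta_pack(s$E0, st$nu, k_from(st$nu) * st$km)
    } else {
      c(log(s$E0), log(k_from(fix_nu) * st$km))
    }
  })
  if (!is.null(init)) {
    stopifnot(inherits(init, "biphasic_params"))
    th0 <- if (is.null(fix_nu)) {
      theta_pack(init$youngs_modulus, max(init$poisson_ratio, 1e-4),
                 init$permeability)
    } else {
      c(log(init$youngs_modulus), log(init$permeability))
    }
    start_list <- c(list(th0), start_list)
  }

  for (th0 in start_list) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = th0, fn = resid_fun,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                             ptol = 1e-12)
      )),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rn <- sqrt(sum(fit$fvec^2))
    if (is.null(best) || rn < best$rn) best <- list(fit = fit, rn = rn)
    # an essentially perfect fit cannot be improved by further starts
    if (best$rn < 1e-8 * length(stress) * max(abs(stress))) break
  }
  if (is.null(best)) {
    abort("Biphasic fit failed from every start.", class = "tissueqc_fit_error")
  }
  th <- best$fit$par
  pp <- if (is.null(fix_nu)) {
    theta_unpack(th)
  } else {
    list(E = exp(th[1]), nu = fix_nu, k = exp(th[2]))
  }
  params <- biphasic_params(pp$E, pp$nu, pp$k)
  fitted <- biphasic_forward(params, proto, time, n_roots)
  structure(
    list(params = params, proto = proto,
         residual_norm = best$rn,
         converged = best$fit$info %in% 1:4,
         plateaued = plateaued,
         n_starts = length(start_list),
         data = tibble(time = time, stress = stress, fitted = fitted)),
    class = "biphasic_fit"
  )
}

#' @export
print.biphasic_fit <- function(x, ...) {
  cat("<biphasic_fit>\n")
  print(x$params)
  cat(sprintf("  residual norm %.4g kPa | converged: %s | plateaued: %s\n",
              x$residual_norm, x$converged, x$plateaued))
  invisible(x)
}

#' Tensile Young's modulus from the linear portion of a stress–strain curve
#'
#' Ordinary least squares slope over the linear region of a tensile test. In
#' `"auto"` mode the contiguous window (at least 30% of the pre-failure
#' points) maximizing R^2 is selected; failure is taken as the stress peak.
#' If no window reaches `min_r2`, a linearity error is raised.
#'
#' @param data A data frame with columns `strain` (dimensionless) and
#'   `stress` (kPa).
#' @param region `"auto"` or a length-2 strain range `c(lo, hi)`.
#' @param min_points Minimum number of points in the fit window.
#' @param min_r2 Minimum acceptable R^2 in auto mode (default 0.9).
#' @param min_frac Minimum window width as a fraction of pre-failure points.
#' @return An object of class `tensile_fit`: `modulus` (kPa), `r_squared`,
#'   `window` (strain range), `n`, and the data. Supports [tidy()]/[glance()].
#' @export
youngs_modulus_tensile <- function(data, region = "auto", min_points = 10,
                                   min_r2 = 0.9, min_frac = 0.3) {
  data <- as.data.frame(data)
  if (!all(c("strain", "stress") %in% names(data))) {
    stop_input("`data` must have columns `strain` and `stress`.")
  }
  strain <- data$strain
  stress <- data$stress
  n_all <- length(strain)
  if (n_all < min_points) stop_input("Too few points for a modulus fit.")

  ols_window <- function(idx) {
    x <- strain[idx]; y <- stress[idx]
    sxx <- sum((x - mean(x))^2)
    if (sxx == 0) return(NULL)
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    syy <- sum((y - mean(y))^2)
    slope <- sxy / sxx
    r2 <- if (syy == 0) 1 else sxy^2 / (sxx * syy)
    list(slope = slope, r2 = r2)
  }

  if (is.numeric(region) && length(region) == 2L) {
    idx <- which(strain >= region[1] & strain <= region[2])
    if (length(idx) < min_points) {
      stop_input("Fewer than `min_points` points in the requested region.")
    }
    f <- ols_window(idx)
    if (is.null(f)) stop_input("Strain is constant in the requested region.")
    win <- range(strain[idx])
    return(new_tensile_fit(f$slope, f$r2, win, length(idx), data))
  }

  i_fail <- which.max(stress)
  pre <- seq_len(i_fail)
  np <- length(pre)
  w_min <- max(min_points, ceiling(min_frac * np))
  if (np < w_min) stop_input("Too few pre-failure points.")
  cx <- cumsum(strain[pre]); cy <- cumsum(stress[pre])
  cxx <- cumsum(strain[pre]^2); cyy <- cumsum(stress[pre]^2)
  cxy <- cumsum(strain[pre] * stress[pre])
  best <- NULL
  for (i in seq_len(np - w_min + 1L)) {
    for (j in seq.int(i + w_min - 1L, np)) {
      n <- j - i + 1L
      sx <- cx[j] - if (i > 1) cx[i - 1] else 0
      sy <- cy[j] - if (i > 1) cy[i - 1] else 0
      sxx <- (cxx[j] - if (i > 1) cxx[i - 1] else 0) - sx^2 / n
      syy <- (cyy[j] - if (i > 1) cyy[i - 1] else 0) - sy^2 / n
      sxy <- (cxy[j] - if (i > 1) cxy[i - 1] else 0) - sx * sy / n
      if (sxx <= 0) next
      r2 <- if (syy <= 0) 1 else sxy^2 / (sxx * syy)
      if (is.null(best) || r2 > best$r2) {
        best <- list(i = i, j = j, r2 = r2, slope = sxy / sxx)
      }
    }
  }
  if (is.null(best) || best$r2 < min_r2) {
    abort("No contiguous window reaches the required linearity (R^2).",
          class = "tissueqc_linearity_error")
  }
  win <- c(strain[best$i], strain[best$j])
  new_tensile_fit(best$slope, best$r2, win, best$j - best$i + 1L, data)
}

new_tensile_fit <- function(modulus, r2, window, n, data) {
  structure(
    list(modulus = modulus, r_squared = r2, window = window, n = n,
         data = as_tibble(data)),
    class = "tensile_fit"
  )
}

#' @export
print.tensile_fit <- function(x, ...) {
  cat(sprintf(
    "<tensile_fit> E = %.4g kPa over strain [%.4g, %.4g] (n = %d, R^2 = %.4f)\n",
    x$modulus, x$window[1], x$window[2], x$n, x$r_squared
  ))
  invisible(x)
}
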