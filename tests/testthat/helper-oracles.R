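# Independent numerical oracles used by the test suite.

# Finite-difference solution of the unconfined-compression biphasic problem:
# radial solid displacement u(r, t) obeys
#   du/dt = k * HA * d/dr[ (1/r) d(r u)/dr ] + (r/2) * deps/dt
# with u(0) = 0 and the stress-free lateral boundary
#   (lambda + 2 mu) u'(a) = lambda * (eps - u(a)/a).
# Mean axial stress magnitude sigma = 2 mu (eps + u(a)/a).
# Crank-Nicolson in time on a uniform radial grid; completely independent of
# the Bessel-series path in the package.
fd_biphasic_stress <- function(E_kPa, nu, k, radius, strain, ramp, t_out,
                               n_r = 150, dt_ramp = ramp / 400,
                               dt_hold = NULL) {
  mu <- E_kPa * 1e3 / (2 * (1 + nu))
  lam <- E_kPa * 1e3 * nu / ((1 + nu) * (1 - 2 * nu))
  HA <- lam + 2 * mu
  kappa <- k * HA # m^2/s
  a <- radius
  h <- a / n_r
  r <- seq_len(n_r) * h # nodes 1..n_r at h..a (u(0)=0)
  gam <- lam / HA

  # spatial operator L u = kappa (u'' + u'/r - u/r^2), ghost-node BC at r=a
  main <- -2 / h^2 - 1 / r^2
  lower <- 1 / h^2 - 1 / (2 * h * r[-1])
  upper <- 1 / h^2 + 1 / (2 * h * r[-n_r])
  # boundary row: u_{N+1} = u_{N-1} + 2 h gam (eps - u_N / a)
  main[n_r] <- -2 / h^2 - 2 * gam / (h * a) - gam / a^2 - 1 / a^2
  lower[n_r - 1] <- 2 / h^2
  bc_coef <- gam * (2 / h + 1 / a) # multiplies eps(t), goes to the RHS
  L <- Matrix::bandSparse(n_r, n_r, k = c(-1, 0, 1),
                          diagonals = list(lower, main, upper)) * kappa

  eps_fun <- function(t) strain * pmin(t, ramp) / ramp
  deps_fun <- function(t) ifelse(t < ramp, strain / ramp, 0)

  t_end <- max(t_out)
  if (is.null(dt_hold)) dt_hold <- max((t_end - ramp) / 1500, dt_ramp)
  times1 <- seq(0, ramp, by = dt_ramp)
  times2 <- if (t_end > ramp) seq(ramp, t_end, by = dt_hold) else numeric(0)
  if (length(times2) && max(times2) < t_end) times2 <- c(times2, t_end)
  steps <- unique(c(times1, times2))

  u <- numeric(n_r)
  I <- Matrix::Diagonal(n_r)
  sig_t <- numeric(length(steps))
  sig_t[1] <- 0
  dt_prev <- -1
  solver <- NULL
  for (s in seq_along(steps)[-1]) {
    t0 <- steps[s - 1]; t1 <- steps[s]
    dt <- t1 - t0
    if (abs(dt - dt_prev) > 1e-12) {
      Aimp <- I - (dt / 2) * L
      solver <- Matrix::lu(Aimp)
      Aexp <- I + (dt / 2) * L
      dt_prev <- dt
    }
    src0 <- r / 2 * deps_fun(t0 + 1e-12) + # row N gets the eps BC source
      kappa * bc_coef * eps_fun(t0) * (seq_len(n_r) == n_r)
    src1 <- r / 2 * deps_fun(t1 - 1e-12) +
      kappa * bc_coef * eps_fun(t1) * (seq_len(n_r) == n_r)
    rhs <- Aexp %*% u + (dt / 2) * (src0 + src1)
    u <- as.numeric(Matrix::solve(solver, rhs))
    sig_t[s] <- 2 * mu * (eps_fun(t1) + u[n_r] / a) / 1e3 # kPa
  }
  approx(steps, sig_t, xout = t_out)$y
}

# brute-force Otsu threshold: maximize between-class variance over all
# candidate levels of a fixed [0, 1] binning (oracle for the segmentation
# threshold)
brute_otsu <- function(img, levels = 256) {
  v <- as.vector(img)
  breaks <- seq(0, 1, length.out = levels + 1)
  h <- hist(v, breaks = breaks, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  best <- -Inf; th <- mids[1]
  for (k in 1:(levels - 1)) {
    w0 <- sum(p[1:k]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(p[1:k] * mids[1:k]) / w0
    m1 <- sum(p[(k + 1):levels] * mids[(k + 1):levels]) / w1
    bc <- w0 * w1 * (m0 - m1)^2
    if (bc > best) { best <- bc; th <- breaks[k + 1] }
  }
  th
}
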