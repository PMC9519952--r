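#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname tidy.biphasic_fit
#' @export
tidy.calibration_model <- function(x, ...) {
  tibble(
    term = c("(Intercept)", x$predictor),
    estimate = c(x$intercept, x$slope),
    std.error = c(NA_real_, x$se_slope),
    p.value = c(NA_real_, x$p_value)
  )
}

#' @rdname glance.biphasic_fit
#' @export
glance.calibration_model <- function(x, ...) {
  tibble(r.squared = x$r_squared, n = x$n, n_dropped = x$n_dropped,
         p.value = x$p_value)
}

#' Tidy fitted tissue models
#'
#' Broom-style one-row-per-term summaries for the package's fitted objects.
#'
#' @param x A `biphasic_fit`, `tensile_fit` or `calibration_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.biphasic_fit <- function(x, ...) {
  tibble(
    term = c("youngs_modulus_kPa", "poisson_ratio", "permeability_m4_Ns"),
    estimate = c(x$params$youngs_modulus, x$params$poisson_ratio,
                 x$params$permeability)
  )
}

#' Glance at fitted tissue models
#'
#' One-row model-level summaries.
#'
#' @param x A `biphasic_fit`, `tensile_fit` or `calibration_model`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.biphasic_fit <- function(x, ...) {
  tibble(residual_norm = x$residual_norm, converged = x$converged,
         plateaued = x$plateaued, n = nrow(x$data), n_starts = x$n_starts)
}

#' @rdname tidy.biphasic_fit
#' @export
tidy.tensile_fit <- function(x, ...) {
  tibble(term = "youngs_modulus_kPa", estimate = x$modulus)
}

#' @rdname glance.biphasic_fit
#' @export
glance.tensile_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, n = x$n,
         window_lo = x$window[1], window_hi = x$window[2])
}
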