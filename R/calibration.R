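#' Simple linear least-squares calibration between two measurements
#'
#' Ordinary least squares of `y` on `x` after pairwise-complete deletion of
#' missing values. `r_squared` is the squared Pearson correlation.
#'
#' @param x,y Numeric vectors of equal length (>= 3 complete pairs).
#' @param predictor,response Names carried into the model (defaults: the
#'   expressions passed as `x` and `y`).
#' @return An object of class `calibration_model`: `slope`, `intercept`,
#'   `r_squared`, `n`, `p_value`, `se_slope`, `x_range`, plus the training
#'   data. Supports [tidy()], [glance()], [predict_from_calibration()],
#'   `autoplot()`.
#' @export
#' @examples
#' m <- fit_linear(c(1, 2, 3), c(1, 3, 2))
#' m$slope # 0.5
fit_linear <- function(x, y, predictor = NULL, response = NULL) {
  if (is.null(predictor)) predictor <- deparse1(substitute(x))
  if (is.null(response)) response <- deparse1(substitute(y))
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y)) {
    stop_input("`x` and `y` must be numeric vectors of equal length.")
  }
  ok <- is.finite(x) & is.finite(y)
  n_dropped <- sum(!ok)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop_input("Need at least 3 complete pairs.")
  if (sd(x) == 0) {
    abort("`x` is constant; the calibration is degenerate.",
          class = "tissueqc_degenerate_fit")
  }
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit)) # "essentially perfect fit" is fine here
  structure(
    list(
      predictor = predictor, response = response,
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      r_squared = unname(sm$r.squared),
      se_slope = unname(sm$coefficients[2, 2]),
      p_value = unname(sm$coefficients[2, 4]),
      n = length(x), n_dropped = n_dropped,
      x_range = range(x),
      data = tibble(x = x, y = y)
    ),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model> %s = %.4g + %.4g * %s | R^2 = %.3f, n = %d, p = %.3g\n",
    x$response, x$intercept, x$slope, x$predictor, x$r_squared, x$n, x$p_value
  ))
  invisible(x)
}

#' Predict a destructive reference value from a calibration model
#'
#' Applies `slope * x + intercept`; predictions outside the training range of
#' the predictor are flagged as extrapolations.
#'
#' @param model A `calibration_model` from [fit_linear()].
#' @param x Numeric vector of predictor values.
#' @return A tibble with `x`, `predicted`, `extrapolated`.
#' @export
predict_from_calibration <- function(model, x) {
  stopifnot(inherits(model, "calibration_model"))
  if (!is.numeric(x)) stop_input("`x` must be numeric.")
  tibble(
    x = x,
    predicted = model$slope * x + model$intercept,
    extrapolated = x < model$x_range[1] | x > model$x_range[2]
  )
}

#' Leave-one-out cross-validated calibration predictions
#'
#' For each complete pair, fits the calibration on all remaining pairs and
#' predicts the held-out response. Useful when judging how well an optical
#' predictor reproduces a destructive reference without training on the
#' sample being predicted; the concordance of `predicted` with `observed`
#' then measures out-of-sample agreement.
#'
#' @param x,y Numeric vectors of equal length (>= 4 complete pairs).
#' @return A tibble with `x`, `observed`, `predicted`.
#' @export
calibration_loocv <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop_input("Need at least 4 complete pairs for leave-one-out.")
  pred <- vapply(seq_len(n), function(i) {
    m <- fit_linear(x[-i], y[-i], predictor = "x", response = "y")
    m$slope * x[i] + m$intercept
  }, numeric(1))
  tibble(x = x, observed = y, predicted = pred)
}

#' Lin's concordance correlation coefficient
#'
#' Agreement statistic between two measurement methods, penalizing both poor
#' correlation and systematic bias:
#' \eqn{\rho_c = 2 s_{xy} / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)}, with
#' population (divide-by-n) moments as in Lin's original formulation. The
#' value lies in `[-1, 1]`; it equals 1 only for `y = x`.
#'
#' @param x,y Numeric vectors of equal length (>= 3 complete pairs).
#' @return The concordance coefficient.
#' @export
#' @examples
#' lin_ccc(1:3, 2:4) # 4/7
lin_ccc <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y)) {
    stop_input("`x` and `y` must be numeric vectors of equal length.")
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop_input("Need at least 3 complete pairs.")
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom == 0) {
    abort("Zero total variance with equal means; concordance undefined.",
          class = "tissueqc_undefined_result")
  }
  2 * sxy / denom
}

#' Calibration table for a linked optical/destructive dataset
#'
#' Fits simple linear calibrations for each requested predictor:response pair,
#' separately per treatment group when a `group` column is given (mirroring a
#' matched-sample design where correlations are modeled per treatment), plus a
#' pooled fit across groups. No multiple-testing correction is applied to the
#' per-pair p-values; they are reported raw.
#'
#' @param data A data frame of linked samples (one row per sample x
#'   timepoint), e.g. from [gen_linked_dataset()].
#' @param pairs Character vector of `"predictor:response"` column pairs, e.g.
#'   `c("ch2_lt:collagen_ww", "ch3_lt:gag_ww")`.
#' @param group Optional name of a grouping column.
#' @return A tibble with one row per pair x group (`group = "pooled"` for the
#'   pooled fit): `predictor`, `response`, `group`, `slope`, `intercept`,
#'   `r_squared`, `n`, `p_value`, and the fitted model in a list column
#'   `model`.
#' @export
calibrate <- function(data, pairs, group = NULL) {
  data <- as.data.frame(data)
  parsed <- strsplit(pairs, ":", fixed = TRUE)
  if (any(lengths(parsed) != 2L)) {
    stop_input('`pairs` entries must look like "predictor:response".')
  }
  groups <- if (is.null(group)) {
    list(pooled = rep(TRUE, nrow(data)))
  } else {
    if (!group %in% names(data)) stop_input("`group` column not found.")
    g <- as.character(data[[group]])
    c(setNames(lapply(unique(g), function(lv) g == lv), unique(g)),
      list(pooled = rep(TRUE, nrow(data))))
  }
  rows <- list()
  for (pr in parsed) {
    if (!all(pr %in% names(data))) {
      stop_input(sprintf("Columns `%s`/`%s` not found.", pr[1], pr[2]))
    }
    for (gname in names(groups)) {
      sel <- groups[[gname]]
      m <- fit_linear(data[[pr[1]]][sel], data[[pr[2]]][sel],
                      predictor = pr[1], response = pr[2])
      rows[[length(rows) + 1L]] <- tibble(
        predictor = pr[1], response = pr[2], group = gname,
        slope = m$slope, intercept = m$intercept, r_squared = m$r_squared,
        n = m$n, p_value = m$p_value, model = list(m)
      )
    }
  }
  dplyr::bind_rows(rows)
}
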