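#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

map_to_df <- function(m) {
  d <- dim(m)
  tibble(
    row = rep(seq_len(d[1]), d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    value = as.vector(m)
  )
}

#' Plot a fluorescence lifetime map
#'
#' @param object A `lifetime_map`.
#' @param ... Unused.
#' @return A ggplot object (axes in µm, missing pixels blank).
#' @export
autoplot.lifetime_map <- function(object, ...) {
  df <- map_to_df(object$lifetime)
  df$x_um <- (df$col - 0.5) * object$pixel_pitch
  df$y_um <- (df$row - 0.5) * object$pixel_pitch
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90",
                                  name = "lifetime (ns)") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("CH%d average lifetime", object$channel),
      x = "x (µm)", y = "y (µm)"
    )
}

#' Plot one frame of a B-mode volume
#'
#' @param object A `bmode_volume`.
#' @param frame Frame index.
#' @param ... Unused.
#' @return A ggplot object (grayscale, axes in µm, depth downward).
#' @export
autoplot.bmode_volume <- function(object, frame = 1, ...) {
  df <- map_to_df(object$frames[, , frame])
  df$x_um <- (df$col - 0.5) * object$voxel_size[2]
  df$z_um <- (df$row - 0.5) * object$voxel_size[1]
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$z_um,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255), name = "level") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("B-mode frame %d", frame),
                  x = "lateral (µm)", y = "depth (µm)")
}

#' Plot a biphasic stress-relaxation fit
#'
#' @param object A `biphasic_fit`.
#' @param ... Unused.
#' @return A ggplot object showing the record and the fitted curve.
#' @export
autoplot.biphasic_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$time, .data$stress)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), color = "firebrick") +
    ggplot2::labs(x = "time (s)", y = "stress (kPa)",
                  title = "Biphasic stress-relaxation fit")
}

#' Plot a tensile modulus fit
#'
#' @param object A `tensile_fit`.
#' @param ... Unused.
#' @return A ggplot object with the selected linear window shaded.
#' @export
autoplot.tensile_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$strain, .data$stress)) +
    ggplot2::annotate("rect", xmin = object$window[1], xmax = object$window[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.15,
                      fill = "steelblue") +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::labs(x = "strain", y = "stress (kPa)",
                  title = sprintf("Tensile fit: E = %.0f kPa", object$modulus))
}

#' Plot a calibration model
#'
#' @param object A `calibration_model`.
#' @param ... Unused.
#' @return A ggplot object of the training pairs and fitted line.
#' @export
autoplot.calibration_model <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         color = "firebrick") +
    ggplot2::labs(
      x = object$predictor, y = object$response,
      title = sprintf("%s vs %s (R² = %.2f)", object$response,
                      object$predictor, object$r_squared)
    )
}
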