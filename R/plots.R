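#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a spectral power distribution
#'
#' @param object An [spd].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot spd
#' @export
autoplot.spd <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$wavelength_nm, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Wavelength (nm)", y = "Relative power",
                  title = object$name) +
    ggplot2::theme_minimal()
}

#' Plot a calibration fit
#'
#' Observed channel means against concentration with the fitted line and
#' the fit's headline numbers.
#'
#' @param object A `calib_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot calib_fit
#' @export
autoplot.calib_fit <- function(object, ...) {
  lab <- sprintf("y = %.4f c + %.2f,  R² = %.4f",
                 object$slope, object$intercept, object$r_squared)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$concentration_mg_dl,
                               y = .data$observed)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = "Direct bilirubin (mg/dL)",
                  y = sprintf("Mean %s-channel grayscale", object$channel),
                  title = lab) +
    ggplot2::theme_minimal()
}

#' Plot a pipeline comparison report
#'
#' Per-channel calibration \eqn{R^2} by light source.
#'
#' @param object A `strip_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot strip_report
#' @export
autoplot.strip_report <- function(object, ...) {
  ggplot2::ggplot(object$ranking,
                  ggplot2::aes(x = .data$light_source, y = .data$r_squared,
                               fill = factor(.data$channel,
                                             levels = c("R", "G", "B")))) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(R = "firebrick", G = "forestgreen",
                                          B = "steelblue"), name = "Channel") +
    ggplot2::labs(x = "Light source",
                  y = expression(R^2 ~ "of calibration line")) +
    ggplot2::theme_minimal()
}

#' Display a strip image
#'
#' @param object A [strip_image].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot strip_image
#' @export
autoplot.strip_image <- function(object, ...) {
  d <- dim(object$pixels)
  df <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  df$fill <- grDevices::rgb(object$pixels[, , 1] / 255,
                            object$pixels[, , 2] / 255,
                            object$pixels[, , 3] / 255)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(fill = df$fill) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
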