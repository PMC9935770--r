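#' Residual standard deviation of a calibration fit
#'
#' The standard deviation of the calibration residuals with two parameters
#' estimated: \eqn{\sqrt{\sum(Y_i - \hat{Y_i})^2 / (n - 2)}}. This is the
#' \eqn{\sigma} that the detection-limit convention divides by the slope.
#'
#' @inheritParams r_squared
#' @return Residual standard deviation in grayscale counts.
#' @export
residual_sd <- function(fit, ds = NULL) {
  stopifnot(inherits(fit, "calib_fit"))
  d <- calib_fit_frame(fit, ds)
  n <- nrow(d)
  if (n <= 2) {
    rlang::abort("Residual SD needs n > 2 (zero degrees of freedom otherwise).",
      class = "bilistrip_error_zero_degrees_of_freedom")
  }
  sqrt(sum((d$observed - d$fitted)^2) / (n - 2))
}

#' Limits of detection and quantification
#'
#' Computes the lowest reliably detectable and quantifiable concentrations
#' from a calibration line's slope and residual noise, under the
#' \eqn{3\sigma} / \eqn{10\sigma} convention:
#' \deqn{LOD = 3\sigma / |slope|, \quad LOQ = 10\sigma / |slope|.}
#' The convention tag is stored in the output so alternative conventions
#' can be added without ambiguity.
#'
#' @param slope Calibration slope, grayscale counts per mg/dL (nonzero).
#'   Alternatively a `calib_fit`, from which slope and residual SD are
#'   taken.
#' @param sigma Residual standard deviation, grayscale counts
#'   (non-negative). Ignored when `slope` is a `calib_fit`.
#' @param convention Detection-limit convention; only `"3sigma/10sigma"` is
#'   currently implemented.
#' @return A one-row tibble: `lod_mg_dl`, `loq_mg_dl`, `sigma_used`,
#'   `slope_used`, `convention`.
#' @examples
#' detection_limits(-6.2971, 1.17551)
#' @export
detection_limits <- function(slope, sigma = NULL,
                             convention = "3sigma/10sigma") {
  if (inherits(slope, "calib_fit")) {
    fit <- slope
    slope <- fit$slope
    if (is.null(sigma)) sigma <- fit$residual_sd
  }
  convention <- match.arg(convention)
  if (!is.numeric(slope) || length(slope) != 1 || is.na(slope) || slope == 0) {
    rlang::abort("`slope` must be a nonzero scalar.",
      class = "bilistrip_error_undefined_limit")
  }
  if (!is.numeric(sigma) || length(sigma) != 1 || is.na(sigma) || sigma < 0) {
    rlang::abort("`sigma` must be a non-negative scalar.",
      class = "bilistrip_error_configuration")
  }
  tibble::tibble(
    lod_mg_dl = 3 * sigma / abs(slope),
    loq_mg_dl = 10 * sigma / abs(slope),
    sigma_used = sigma, slope_used = slope,
    convention = convention)
}
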