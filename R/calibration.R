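#' Fit a linear calibration curve for one channel
#'
#' Ordinary least-squares fit of a channel's mean grayscale against
#' concentration: \eqn{Y = intercept + slope \cdot c}. The coefficient of
#' determination is the regression-sum-of-squares form
#' \eqn{R^2 = \sum(\hat{Y_i} - \bar{Y})^2 / \sum(Y_i - \bar{Y})^2}
#' (see [r_squared()]), and the residual standard deviation is
#' \eqn{\sqrt{SSE / (n - 2)}} (see [residual_sd()]).
#'
#' @param ds A calibration dataset: a data frame with a
#'   `concentration_mg_dl` column and per-channel mean columns `mean_R`,
#'   `mean_G`, `mean_B` (only the fitted channel's column is required), such
#'   as produced by [generate_calibration_table()] or the pipeline's
#'   per-image statistics. An optional `light_source` attribute or column is
#'   carried through.
#' @param channel `"R"`, `"G"` or `"B"`.
#' @return An object of class `calib_fit` with elements `channel`,
#'   `light_source`, `slope`, `intercept`, `r_squared`, `residual_sd`, `n`
#'   and a `data` tibble (`concentration_mg_dl`, `observed`, `fitted`).
#'   Use [tidy()] / [glance()] for tibble views.
#' @examples
#' ds <- generate_calibration_table(default_concentration_series(),
#'                                  response_preset("mini_led", "G"),
#'                                  sigma = 0, seed = 1)
#' glance(fit_line(ds, "G"))
#' @export
fit_line <- function(ds, channel = "G") {
  col <- paste0("mean_", channel)
  if (!all(c("concentration_mg_dl", col) %in% names(ds))) {
    rlang::abort(sprintf("Dataset must have columns concentration_mg_dl and %s.", col),
      class = "bilistrip_error_invalid_dataset")
  }
  conc <- as.numeric(ds$concentration_mg_dl)
  y <- as.numeric(ds[[col]])
  keep <- !is.na(conc) & !is.na(y)
  conc <- conc[keep]; y <- y[keep]
  n <- length(y)
  if (n < 3) {
    rlang::abort("At least 3 records are needed to fit a calibration line.",
      class = "bilistrip_error_insufficient_data")
  }
  if (length(unique(conc)) < 2) {
    rlang::abort("All concentrations are equal; the design is singular.",
      class = "bilistrip_error_singular_design")
  }
  m <- stats::lm(y ~ conc)
  light <- attr(ds, "light_source")
  if (is.null(light) && "light_source" %in% names(ds)) {
    light <- unique(as.character(ds$light_source))[1]
  }
  fit <- structure(
    list(channel = channel,
         light_source = light %||% NA_character_,
         slope = unname(stats::coef(m)[2]),
         intercept = unname(stats::coef(m)[1]),
         r_squared = NA_real_, residual_sd = NA_real_, n = n,
         data = tibble::tibble(concentration_mg_dl = conc, observed = y,
                               fitted = unname(stats::fitted(m)))),
    class = "calib_fit")
  fit$r_squared <- tryCatch(r_squared(fit),
    bilistrip_error_undefined_r_squared = function(e) NA_real_)
  fit$residual_sd <- residual_sd(fit)
  fit
}

#' @export
print.calib_fit <- function(x, ...) {
  cat(sprintf(
    "<calib_fit> %s channel%s: y = %.4f c + %.4f  (R2 = %s, s = %.4f, n = %d)\n",
    x$channel,
    if (is.na(x$light_source)) "" else paste0(" / ", x$light_source),
    x$slope, x$intercept,
    ifelse(is.na(x$r_squared), "NA", sprintf("%.4f", x$r_squared)),
    x$residual_sd, x$n))
  invisible(x)
}

#' Coefficient of determination of a calibration fit
#'
#' Computes \eqn{R^2} as the ratio of the regression sum of squares to the
#' total sum of squares,
#' \eqn{\sum(\hat{Y_i} - \bar{Y})^2 / \sum(Y_i - \bar{Y})^2}, from the
#' fitted values — not via the squared-correlation shortcut, so the
#' algebraic identity with \eqn{1 - SSE/SST} is a testable property rather
#' than a definition.
#'
#' @param fit A `calib_fit`.
#' @param ds Optional dataset to recompute fitted values against; defaults
#'   to the data stored in the fit.
#' @return \eqn{R^2} in \[0, 1\].
#' @export
r_squared <- function(fit, ds = NULL) {
  stopifnot(inherits(fit, "calib_fit"))
  d <- calib_fit_frame(fit, ds)
  sst <- sum((d$observed - mean(d$observed))^2)
  if (sst <= 0) {
    rlang::abort("All observations are equal; R-squared is undefined.",
      class = "bilistrip_error_undefined_r_squared")
  }
  sum((d$fitted - mean(d$observed))^2) / sst
}

# observed/fitted pairs, either stored in the fit or recomputed on ds
calib_fit_frame <- function(fit, ds = NULL) {
  if (is.null(ds)) return(fit$data)
  col <- paste0("mean_", fit$channel)
  conc <- as.numeric(ds$concentration_mg_dl)
  y <- as.numeric(ds[[col]])
  tibble::tibble(concentration_mg_dl = conc, observed = y,
                 fitted = fit$intercept + fit$slope * conc)
}

#' Rank channels by calibration linearity
#'
#' Orders the per-channel calibration fits of one or more light sources by
#' descending \eqn{R^2}. Ties are broken by channel order R, G, B so the
#' ranking is deterministic.
#'
#' @param fits A list of `calib_fit` objects (or a single fit).
#' @return A tibble with one row per fit - `light_source`, `channel`,
#'   `slope`, `intercept`, `r_squared`, `residual_sd`, `n`, `rank` - sorted
#'   by light source, then rank.
#' @export
rank_channels <- function(fits) {
  if (inherits(fits, "calib_fit")) fits <- list(fits)
  if (length(fits) < 1) {
    rlang::abort("At least one fit is required.",
      class = "bilistrip_error_insufficient_data")
  }
  tab <- purrr::map_dfr(fits, glance)
  tab |>
    dplyr::mutate(channel = factor(.data$channel, levels = c("R", "G", "B"))) |>
    dplyr::group_by(.data$light_source) |>
    dplyr::arrange(dplyr::desc(.data$r_squared), .data$channel,
                   .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::mutate(channel = as.character(.data$channel))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a calibration fit
#'
#' @param x A `calib_fit`.
#' @param ... Unused.
#' @return A two-row tibble of model terms (`intercept`, `slope`) and
#'   estimates.
#' @method tidy calib_fit
#' @export
tidy.calib_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' One-row summary of a calibration fit
#'
#' @param x A `calib_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `light_source`, `channel`, `slope`,
#'   `intercept`, `r_squared`, `residual_sd`, `n`.
#' @method glance calib_fit
#' @export
glance.calib_fit <- function(x, ...) {
  tibble::tibble(light_source = x$light_source, channel = x$channel,
                 slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, residual_sd = x$residual_sd,
                 n = x$n)
}

#' Read or write a calibration dataset as CSV
#'
#' The exchange format has columns `concentration_mg_dl`, `mean_R`,
#' `mean_G`, `mean_B` and optionally `sd_R`, `sd_G`, `sd_B`, `n_pixels`,
#' `light_source`.
#'
#' @param path CSV file path.
#' @return A tibble (with attribute `light_source` when the column is
#'   constant).
#' @export
read_calibration_csv <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  if (!"concentration_mg_dl" %in% names(tab)) {
    rlang::abort(sprintf("%s: missing concentration_mg_dl column.", path),
      class = "bilistrip_error_io")
  }
  if ("light_source" %in% names(tab) &&
      length(unique(tab$light_source)) == 1) {
    attr(tab, "light_source") <- tab$light_source[1]
  }
  tab
}

#' @rdname read_calibration_csv
#' @param ds Calibration dataset to write.
#' @export
write_calibration_csv <- function(ds, path) {
  out <- as.data.frame(ds)
  if (!"light_source" %in% names(out) && !is.null(attr(ds, "light_source"))) {
    out$light_source <- attr(ds, "light_source")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
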