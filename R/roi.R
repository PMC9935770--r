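#' Circular region-of-interest mask
#'
#' Builds the sampling mask for the circular test paper inside a square
#' analysis window. A pixel is included iff its centre lies within
#' `diameter_px / 2` of the disc centre (Euclidean distance, boundary ties
#' included). Coordinates are 0-based and row-major with pixel centres at
#' integer positions. The defaults - a 130 px window (16,900 total points)
#' holding a 130 px disc - correspond to a 30 mm paper imaged at about
#' 0.23 mm per pixel.
#'
#' @param window_side_px Side of the square analysis window, px.
#' @param diameter_px Disc diameter, px; must not exceed the window side.
#' @param center `(row, col)` of the disc centre in window coordinates;
#'   default the window centre `(side - 1) / 2`.
#' @param origin `(row, col)` of the window's top-left pixel inside the full
#'   image (0-based); default `c(0, 0)`.
#' @return An object of class `roi_mask`: window origin and side, logical
#'   inclusion `flags` (side x side), and the included-pixel `count`.
#' @examples
#' circular_roi_mask(130, 130)$count
#' @export
circular_roi_mask <- function(window_side_px, diameter_px = window_side_px,
                              center = NULL, origin = c(0, 0)) {
  if (diameter_px > window_side_px) {
    rlang::abort("Disc diameter exceeds the analysis window.",
      class = "bilistrip_error_geometry")
  }
  if (window_side_px < 1 || diameter_px <= 0) {
    rlang::abort("Window side and diameter must be positive.",
      class = "bilistrip_error_geometry")
  }
  if (is.null(center)) center <- rep((window_side_px - 1) / 2, 2)
  rows <- matrix(0:(window_side_px - 1), window_side_px, window_side_px)
  cols <- t(rows)
  flags <- (rows - center[1])^2 + (cols - center[2])^2 <= (diameter_px / 2)^2
  structure(
    list(origin = as.numeric(origin), side = as.integer(window_side_px),
         flags = flags, count = sum(flags)),
    class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %dx%d window at (%g, %g), %d of %d pixels included\n",
              x$side, x$side, x$origin[1], x$origin[2], x$count, x$side^2))
  invisible(x)
}

#' Export an ROI mask as an image
#'
#' Writes the inclusion flags as a 0/255 grayscale PNG for visual
#' inspection.
#'
#' @param mask An `roi_mask`.
#' @param path Output PNG path.
#' @export
write_roi_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"))
  png::writePNG(mask$flags * 1.0, target = path)
  invisible(path)
}

#' Per-channel grayscale statistics over an ROI
#'
#' Computes the arithmetic mean and population standard deviation of the
#' raw stored 8-bit values of each colour channel over the mask's included
#' pixels. No gamma linearization is applied: the grayscale value is the
#' stored digital count, the convention of phone RGB-analysis tools.
#'
#' @param img A [strip_image] or a `height x width x 3` array of 0-255
#'   values.
#' @param mask An `roi_mask` whose window lies within the image; default a
#'   full-window disc of side `min(dim)` rounded down to the image, centred.
#' @return A one-row tibble: `mean_R`, `mean_G`, `mean_B`, `sd_R`, `sd_G`,
#'   `sd_B`, `n_pixels`, plus `light_source` and `concentration_mg_dl` when
#'   the image carries them.
#' @export
channel_stats <- function(img, mask = NULL) {
  px <- if (inherits(img, "strip_image")) img$pixels else img
  if (length(dim(px)) != 3 || dim(px)[3] != 3) {
    rlang::abort("`img` must be a height x width x 3 array or strip_image.",
      class = "bilistrip_error_invalid_image")
  }
  h <- dim(px)[1]; w <- dim(px)[2]
  if (is.null(mask)) {
    side <- min(h, w)
    mask <- circular_roi_mask(side, side,
                              origin = c(floor((h - side) / 2),
                                         floor((w - side) / 2)))
  }
  r0 <- mask$origin[1]; c0 <- mask$origin[2]
  if (r0 < 0 || c0 < 0 || r0 + mask$side > h || c0 + mask$side > w) {
    rlang::abort("ROI window does not lie within the image.",
      class = "bilistrip_error_geometry")
  }
  if (mask$count == 0) {
    rlang::abort("ROI mask includes no pixels.",
      class = "bilistrip_error_empty_roi")
  }
  win <- px[(r0 + 1):(r0 + mask$side), (c0 + 1):(c0 + mask$side), , drop = FALSE]
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  vals <- lapply(1:3, function(k) win[, , k][mask$flags])
  out <- tibble::tibble(
    mean_R = mean(vals[[1]]), mean_G = mean(vals[[2]]), mean_B = mean(vals[[3]]),
    sd_R = pop_sd(vals[[1]]), sd_G = pop_sd(vals[[2]]), sd_B = pop_sd(vals[[3]]),
    n_pixels = mask$count)
  if (inherits(img, "strip_image")) {
    out$light_source <- img$light_source
    out$concentration_mg_dl <- img$concentration_mg_dl
  }
  out
}
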