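#' Packaged channel response presets
#'
#' Linear concentration-to-grayscale responses for each light source and
#' colour channel, used by the synthetic calibration-data generators. Green
#' (G) channel lines reproduce the empirical calibration equations reported
#' for each light source (mini-LED: \eqn{y = -6.2971x + 221.81}; halogen H2:
#' \eqn{y = -6.2029x + 221.72}; deuterium D2: \eqn{y = -1.8078x + 231.56}).
#' Red and blue channel lines have no published equations; the packaged
#' defaults are chosen so that the per-channel coefficient-of-determination
#' ordering G > R > B holds for every light source (see the methods
#' vignette).
#'
#' Two residual-noise variants are packaged for the G channel:
#' \describe{
#'   \item{`"r2"`}{standard deviations (1.117 mini-LED, 1.362 H2, 0.625 D2)
#'     back-computed so the expected fitted R-squared under the default
#'     12-point series matches the reported values 0.9313 / 0.8984 / 0.7809.}
#'   \item{`"lod"`}{standard deviations (1.17551 mini-LED, 1.42667 H2)
#'     back-computed from the reported detection limits via
#'     \eqn{LOD = 3\sigma/|slope|}. Not available for D2, which has no
#'     reported detection limit.}
#' }
#' The two constraints are mutually inconsistent by about 5% under the
#' assumed evenly spaced design, so both are shipped and labelled.
#'
#' @param light_source One of `"d2"`, `"h2"`, `"mini_led"`.
#' @param channel One of `"R"`, `"G"`, `"B"`.
#' @param sigma Which packaged residual-sd variant to attach: `"r2"`
#'   (default) or `"lod"` (G channel only).
#' @return A one-row tibble of class `response_preset` with columns
#'   `light_source`, `channel`, `slope`, `intercept`, `residual_sd`,
#'   `sigma_kind`.
#' @examples
#' response_preset("mini_led", "G")
#' @export
response_preset <- function(light_source, channel = "G", sigma = c("r2", "lod")) {
  sigma <- match.arg(sigma)
  tab <- response_presets()
  row <- tab[tab$light_source == light_source & tab$channel == channel, ]
  if (nrow(row) != 1) {
    rlang::abort(
      sprintf("No packaged response preset for light source \"%s\", channel \"%s\".",
              light_source, channel),
      class = "bilistrip_error_preset_not_found")
  }
  sd <- if (sigma == "r2") row$sigma_r2 else row$sigma_lod
  if (is.na(sd)) {
    rlang::abort(
      sprintf("No \"%s\" residual-sd variant packaged for %s/%s.",
              sigma, light_source, channel),
      class = "bilistrip_error_preset_not_found")
  }
  out <- tibble::tibble(
    light_source = row$light_source, channel = row$channel,
    slope = row$slope, intercept = row$intercept,
    residual_sd = sd, sigma_kind = sigma)
  class(out) <- c("response_preset", class(out))
  out
}

#' @rdname response_preset
#' @return For `response_presets()`, the full preset table with both
#'   residual-sd variants as columns `sigma_r2` and `sigma_lod`.
#' @export
response_presets <- function() {
  tibble::tribble(
    ~light_source, ~channel, ~slope,  ~intercept, ~sigma_r2, ~sigma_lod,
    "mini_led",    "G",      -6.2971, 221.81,     1.117,     1.17551,
    "h2",          "G",      -6.2029, 221.72,     1.362,     1.42667,
    "d2",          "G",      -1.8078, 231.56,     0.625,     NA,
    "mini_led",    "R",      -5.1,    227,        1.5,       NA,
    "mini_led",    "B",      -1.7,    158,        1.7,       NA,
    "h2",          "R",      -5.0,    225,        1.5625,    NA,
    "h2",          "B",      -1.9,    150,        1.8095,    NA,
    "d2",          "R",      -1.35,   204,        0.5510,    NA,
    "d2",          "B",      -1.1,    218,        1.4667,    NA
  )
}

#' Default calibration concentration series
#'
#' Twelve standard-solution concentrations evenly spaced over 0.1 to
#' 2.0 mg/dL inclusive (step 19/110 mg/dL), the series the calibration
#' experiments assume.
#'
#' @return Strictly increasing numeric vector of length 12 (mg/dL).
#' @export
default_concentration_series <- function() {
  seq(0.1, 2.0, length.out = 12)
}

#' Expected grayscale at a concentration
#'
#' Evaluates a channel response preset's line \eqn{slope \cdot c + intercept}
#' and clips the result to the representable 8-bit range \[0, 255\].
#'
#' @param c_mg_dl Concentration(s), mg/dL, non-negative.
#' @param preset A [response_preset].
#' @return Expected mean grayscale value(s) in \[0, 255\].
#' @examples
#' mean_gray(1.0, response_preset("mini_led", "G"))
#' @export
mean_gray <- function(c_mg_dl, preset) {
  if (any(c_mg_dl < 0)) {
    rlang::abort("Concentrations must be non-negative.",
      class = "bilistrip_error_domain")
  }
  pmin(pmax(preset$slope * c_mg_dl + preset$intercept, 0), 255)
}

#' Simulate a calibration table for one channel
#'
#' Draws one record per concentration with channel mean
#' `mean_gray(c, preset) + e`, `e ~ Normal(0, sigma^2)`, clipped to
#' \[0, 255\]. This is the measurement-level stand-in for photographing a
#' dilution series of reacted test papers and averaging each image's region
#' of interest.
#'
#' @param concs Non-empty numeric vector of concentrations (mg/dL).
#' @param preset A [response_preset].
#' @param sigma Residual standard deviation in grayscale counts; defaults to
#'   the preset's packaged value.
#' @param seed Optional integer seed; when given, the table is reproducible
#'   and the global RNG state is left untouched.
#' @return A tibble with columns `concentration_mg_dl` and `mean_<channel>`,
#'   with the light source stored in attribute `light_source`.
#' @examples
#' generate_calibration_table(default_concentration_series(),
#'                            response_preset("mini_led", "G"), seed = 1)
#' @export
generate_calibration_table <- function(concs, preset, sigma = preset$residual_sd,
                                       seed = NULL) {
  if (length(concs) < 1) {
    rlang::abort("`concs` must be non-empty.", class = "bilistrip_error_domain")
  }
  if (!is.numeric(sigma) || length(sigma) != 1 || is.na(sigma) || sigma < 0) {
    rlang::abort("`sigma` must be a non-negative scalar.",
      class = "bilistrip_error_configuration")
  }
  draw <- function() stats::rnorm(length(concs), 0, sigma)
  eps <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  vals <- pmin(pmax(mean_gray(concs, preset) + eps, 0), 255)
  out <- tibble::tibble(concentration_mg_dl = as.numeric(concs))
  out[[paste0("mean_", preset$channel)]] <- vals
  attr(out, "light_source") <- preset$light_source
  out
}

#' Simulate a three-channel calibration table for one light source
#'
#' Like [generate_calibration_table()] but for all three channels at once,
#' with the strip-level noise shared across channels: one standard-normal
#' draw per strip, scaled by each channel's residual standard deviation.
#' This emulates frame-level illumination and exposure fluctuation, which
#' moves all channels of one photograph together, and it is what the image
#' fixture generator uses; it makes the relative linearity of the channels
#' (the R-squared ordering) a property of the channel responses rather than
#' of the particular noise draw.
#'
#' @inheritParams generate_calibration_table
#' @param light_source One of `"d2"`, `"h2"`, `"mini_led"`.
#' @param sigma_kind Which packaged residual-sd variant to use (`"r2"` or
#'   `"lod"`); the G channel only has both, so `"r2"` is the default.
#' @return A tibble with columns `concentration_mg_dl`, `mean_R`, `mean_G`,
#'   `mean_B`; attribute `light_source`.
#' @export
generate_strip_responses <- function(concs, light_source, seed = NULL,
                                     sigma_kind = "r2") {
  if (length(concs) < 1) {
    rlang::abort("`concs` must be non-empty.", class = "bilistrip_error_domain")
  }
  draw <- function() stats::rnorm(length(concs))
  eps <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  strip_responses_from_noise(concs, light_source, eps, sigma_kind)
}

# shared-noise channel means given the per-strip standard-normal draws
strip_responses_from_noise <- function(concs, light_source, eps,
                                       sigma_kind = "r2") {
  out <- tibble::tibble(concentration_mg_dl = as.numeric(concs))
  for (ch in c("R", "G", "B")) {
    p <- response_preset(light_source, ch,
                         sigma = if (ch == "G") sigma_kind else "r2")
    out[[paste0("mean_", ch)]] <-
      pmin(pmax(mean_gray(concs, p) + p$residual_sd * eps, 0), 255)
  }
  attr(out, "light_source") <- light_source
  out
}

# Biliverdin-like absorbance shape (unit amplitude): a broad band peaked in
# the red/orange plus a half-amplitude secondary violet band, the absorption
# pattern of a blue-green pigment. FWHM 100 nm for both bands.
biliverdin_absorbance_shape <- function(wavelengths_nm) {
  s <- 100 / (2 * sqrt(2 * log(2)))
  exp(-((wavelengths_nm - 660)^2) / (2 * s^2)) +
    0.5 * exp(-((wavelengths_nm - 400)^2) / (2 * s^2))
}

# flat blank-paper reflectance level
BLANK_REFLECTANCE <- 0.92

#' Reflectance of the reacted test paper
#'
#' Beer-Lambert model of the biliverdin-stained paper:
#' \eqn{R(\lambda; c) = R_0 \cdot 10^{-c \, k \, a(\lambda)}}, with flat
#' blank-paper reflectance \eqn{R_0 = 0.92}, a fixed absorbance shape
#' \eqn{a(\lambda)} (principal band at 660 nm, half-amplitude secondary band
#' at 400 nm, both 100 nm FWHM - the signature of a blue-green pigment), and
#' amplitude \eqn{k} per mg/dL. By default \eqn{k} is calibrated once so
#' that, rendered under the mini-LED preset with a calibrated exposure, the
#' green-channel response over the default concentration series matches the
#' mini-LED green calibration line's slope.
#'
#' @param c_mg_dl Concentration, mg/dL, non-negative scalar.
#' @param absorbance_scale Amplitude \eqn{k} (per mg/dL); `NULL` for the
#'   mini-LED-calibrated default.
#' @param wavelengths_nm Wavelength grid, nm.
#' @return A [reflectance_spectrum].
#' @export
biliverdin_reflectance <- function(c_mg_dl, absorbance_scale = NULL,
                                   wavelengths_nm = seq(380, 780, by = 1)) {
  if (!is.numeric(c_mg_dl) || length(c_mg_dl) != 1 || is.na(c_mg_dl) ||
      c_mg_dl < 0) {
    rlang::abort("`c_mg_dl` must be a non-negative scalar concentration.",
      class = "bilistrip_error_domain")
  }
  if (is.null(absorbance_scale)) {
    absorbance_scale <- render_calibration("mini_led")$absorbance_scale
  }
  a <- biliverdin_absorbance_shape(wavelengths_nm)
  reflectance_spectrum(
    wavelengths_nm,
    BLANK_REFLECTANCE * 10^(-c_mg_dl * absorbance_scale * a))
}

# cache for per-light-source render calibrations
.render_cal_cache <- new.env(parent = emptyenv())

#' Exposure and absorbance calibration for spectral strip rendering
#'
#' For a light source and camera model, solves for (1) the exposure factor
#' that makes the rendered blank paper's green channel hit the light
#' source's green-line intercept, and (2) the absorbance amplitude that
#' makes the rendered green-channel response over the default concentration
#' series match the light source's green-line slope (ordinary least squares
#' on the continuous, pre-quantization channel values). Results are cached
#' per light source and camera configuration.
#'
#' @param light_source One of `"d2"`, `"h2"`, `"mini_led"`.
#' @param cam A [camera_response]; its `exposure_scale` is ignored (the
#'   calibrated value replaces it).
#' @return A list with `exposure_scale` and `absorbance_scale`.
#' @export
render_calibration <- function(light_source, cam = camera_response()) {
  key <- paste(light_source,
               paste(signif(c(cam$sensitivities[c(1, 200, 401), ]), 8), collapse = ","),
               sep = "|")
  hit <- .render_cal_cache[[key]]
  if (!is.null(hit)) return(hit)

  preset <- response_preset(light_source, "G")
  light <- spd_preset(light_source)
  g <- cam$wavelengths_nm
  p <- stats::approx(light$wavelengths_nm, light$intensities, xout = g,
                     yleft = 0, yright = 0)$y
  p[is.na(p)] <- 0
  sens_g <- cam$sensitivities[, "G"]
  a <- biliverdin_absorbance_shape(g)

  # green linear signal at concentration c for absorbance amplitude k
  lin_g <- function(c_mg_dl, k) {
    trapz(g, p * BLANK_REFLECTANCE * 10^(-c_mg_dl * k * a) * sens_g)
  }
  blank <- lin_g(0, 0)
  if (blank <= 0) {
    rlang::abort(sprintf(
      "Light source \"%s\" has no green-band power; cannot calibrate exposure.",
      light_source), class = "bilistrip_error_degenerate_spectrum")
  }
  exposure <- srgb_decode(preset$intercept / 255) / blank

  concs <- default_concentration_series()
  digital_g <- function(k) {
    lin <- vapply(concs, lin_g, numeric(1), k = k)
    255 * srgb_encode(pmin(pmax(lin * exposure, 0), 1))
  }
  slope_of <- function(k) stats::coef(stats::lm(digital_g(k) ~ concs))[[2]]
  k <- stats::uniroot(function(k) slope_of(k) - preset$slope,
                      lower = 1e-6, upper = 5, tol = 1e-10)$root

  out <- list(exposure_scale = exposure, absorbance_scale = k)
  .render_cal_cache[[key]] <- out
  out
}

#' Strip image objects
#'
#' A `strip_image` is an 8-bit, three-channel raster of one photographed
#' test paper plus acquisition metadata.
#'
#' @param pixels Integer array `height x width x 3` with values in 0-255.
#' @param light_source Light-source label.
#' @param concentration_mg_dl True concentration (mg/dL) or `NA`.
#' @param pixel_pitch_mm Physical size of one pixel (mm).
#' @param seed Seed used to generate the image, or `NA`.
#' @return An object of class `strip_image`.
#' @export
strip_image <- function(pixels, light_source = NA_character_,
                        concentration_mg_dl = NA_real_,
                        pixel_pitch_mm = NA_real_, seed = NA_integer_) {
  if (length(dim(pixels)) != 3 || dim(pixels)[3] != 3) {
    rlang::abort("`pixels` must be a height x width x 3 array.",
      class = "bilistrip_error_invalid_image")
  }
  if (any(pixels < 0) || any(pixels > 255)) {
    rlang::abort("Pixel values must lie in [0, 255].",
      class = "bilistrip_error_invalid_image")
  }
  structure(
    list(pixels = pixels, light_source = light_source,
         concentration_mg_dl = concentration_mg_dl,
         pixel_pitch_mm = pixel_pitch_mm, seed = seed),
    class = "strip_image")
}

#' @export
print.strip_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<strip_image> %dx%d px, light source %s, %s mg/dL\n",
              d[1], d[2], x$light_source,
              ifelse(is.na(x$concentration_mg_dl), "?",
                     format(x$concentration_mg_dl))))
  invisible(x)
}

# default background gray of the rendered scene
STRIP_BACKGROUND <- c(30L, 30L, 30L)

# paint a centred disc of one (continuous) colour, add per-pixel Gaussian
# noise per channel, clip and quantize; shared by both strip renderers
paint_disc <- function(color, size_px, diameter_px, noise_sd,
                       background = STRIP_BACKGROUND) {
  if (diameter_px > size_px) {
    rlang::abort("Disc diameter exceeds the image size.",
      class = "bilistrip_error_geometry")
  }
  ctr <- (size_px - 1) / 2
  rows <- matrix(0:(size_px - 1), size_px, size_px)
  cols <- t(rows)
  inside <- (rows - ctr)^2 + (cols - ctr)^2 <= (diameter_px / 2)^2
  img <- array(0, dim = c(size_px, size_px, 3))
  for (k in 1:3) {
    plane <- matrix(background[k], size_px, size_px)
    plane[inside] <- color[k]
    if (noise_sd > 0) {
      plane <- plane + matrix(stats::rnorm(size_px^2, 0, noise_sd),
                              size_px, size_px)
    }
    img[, , k] <- plane
  }
  clipped <- mean(img < 0 | img > 255)
  if (clipped > 0.01) {
    rlang::warn(sprintf("%.1f%% of pixels clipped at 0/255.", 100 * clipped))
  }
  array(as.integer(round_half_up(pmin(pmax(img, 0), 255))), dim = dim(img))
}

#' Render a synthetic test-strip photograph from spectra
#'
#' Physically motivated renderer: the centred disc (the 30 mm test paper)
#' takes the colour of the light source's spectrum multiplied by the
#' Beer-Lambert paper reflectance at the given concentration, rendered
#' through the camera model with the light source's calibrated exposure
#' (see [render_calibration()]); the background is a fixed dark gray.
#' Per-pixel i.i.d. Gaussian noise is added per channel, then values are
#' clipped to \[0, 255\] and quantized.
#'
#' @param c_mg_dl Concentration, mg/dL.
#' @param light Light-source name (`"d2"`, `"h2"`, `"mini_led"`) or an [spd]
#'   (an `spd` requires an explicit `exposure_scale` and `absorbance_scale`).
#' @param cam A [camera_response].
#' @param noise_sd Per-pixel noise standard deviation, grayscale counts.
#' @param size_px Image side length, px.
#' @param diameter_px Disc diameter, px (default 130, the 30 mm paper).
#' @param seed Optional integer seed for the pixel noise.
#' @param exposure_scale,absorbance_scale Optional overrides of the
#'   calibrated values.
#' @return A [strip_image]. The pixel pitch is `30 / diameter_px` mm.
#' @export
render_strip_image <- function(c_mg_dl, light = "mini_led",
                               cam = camera_response(), noise_sd = 2,
                               size_px = 140, diameter_px = 130, seed = NULL,
                               exposure_scale = NULL, absorbance_scale = NULL) {
  if (is.character(light)) {
    cal <- render_calibration(light, cam)
    if (is.null(exposure_scale)) exposure_scale <- cal$exposure_scale
    if (is.null(absorbance_scale)) absorbance_scale <- cal$absorbance_scale
    light_name <- light
    light <- spd_preset(light)
  } else {
    stopifnot(inherits(light, "spd"))
    if (is.null(exposure_scale) || is.null(absorbance_scale)) {
      rlang::abort(
        "An spd light needs explicit `exposure_scale` and `absorbance_scale`.",
        class = "bilistrip_error_configuration")
    }
    light_name <- light$name
  }
  refl <- biliverdin_reflectance(c_mg_dl, absorbance_scale)
  cam$exposure_scale <- exposure_scale
  color <- spd_to_srgb(spectral_product(light, refl), cam)
  render <- function() paint_disc(color, size_px, diameter_px, noise_sd)
  px <- if (is.null(seed)) render() else withr::with_seed(seed, render())
  strip_image(px, light_source = light_name, concentration_mg_dl = c_mg_dl,
              pixel_pitch_mm = 30 / diameter_px,
              seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

# preset-driven strip painting: disc channel means follow the packaged
# response lines plus shared strip-level noise (eps, standard normal);
# per-pixel noise then acts as dither so the ROI mean tracks the target
render_preset_strip <- function(c_mg_dl, light_source, eps = 0, noise_sd = 2,
                                size_px = 140, diameter_px = 130, seed = NULL) {
  color <- vapply(c("R", "G", "B"), function(ch) {
    p <- response_preset(light_source, ch)
    min(max(mean_gray(c_mg_dl, p) + p$residual_sd * eps, 0), 255)
  }, numeric(1))
  render <- function() paint_disc(color, size_px, diameter_px, noise_sd)
  px <- if (is.null(seed)) render() else withr::with_seed(seed, render())
  strip_image(px, light_source = light_source, concentration_mg_dl = c_mg_dl,
              pixel_pitch_mm = 30 / diameter_px,
              seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Read and write strip images
#'
#' Images are exchanged as 8-bit RGB PNG (TIFF is also accepted on read when
#' the tiff package is installed). `write_strip_png()` also writes a JSON
#' metadata sidecar (`<image>.json`: light source, concentration, pixel
#' pitch, seed) next to the image.
#'
#' @param img A [strip_image].
#' @param path Image file path.
#' @param sidecar Write the JSON sidecar? Default `TRUE`.
#' @return `read_strip_image()` returns a [strip_image] (metadata populated
#'   from the sidecar when present).
#' @export
write_strip_png <- function(img, path, sidecar = TRUE) {
  stopifnot(inherits(img, "strip_image"))
  png::writePNG(img$pixels / 255, target = path)
  if (sidecar) {
    meta <- list(light_source = img$light_source,
                 concentration_mg_dl = img$concentration_mg_dl,
                 pixel_pitch_mm = img$pixel_pitch_mm, seed = img$seed)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname write_strip_png
#' @export
read_strip_image <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("Image file not found: %s", path),
      class = "bilistrip_error_io")
  }
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      rlang::abort("Reading TIFF requires the tiff package.",
        class = "bilistrip_error_io")
    }
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(raw)) == 2) raw <- array(rep(raw, 3), dim = c(dim(raw), 3))
  if (dim(raw)[3] > 3) raw <- raw[, , 1:3, drop = FALSE]
  px <- array(as.integer(round_half_up(raw * 255)), dim = dim(raw))
  img <- strip_image(px)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    img$light_source <- meta$light_source %||% NA_character_
    img$concentration_mg_dl <- as.numeric(meta$concentration_mg_dl %||% NA)
    img$pixel_pitch_mm <- as.numeric(meta$pixel_pitch_mm %||% NA)
    img$seed <- as.integer(meta$seed %||% NA)
  }
  img
}

`%||%` <- function(a, b) if (is.null(a)) b else a
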