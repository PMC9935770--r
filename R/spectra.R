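#' Spectral power distributions
#'
#' An `spd` holds a relative emission spectrum \eqn{P(\lambda)} on a strictly
#' increasing wavelength grid. Intensities are non-negative and carry
#' arbitrary (relative) units: only ratios matter downstream, both for
#' chromaticity and for camera rendering, where absolute scale is absorbed by
#' the exposure term.
#'
#' @param wavelengths_nm Strictly increasing numeric vector of wavelengths (nm).
#' @param intensities Non-negative numeric vector, same length.
#' @param name Free-text label for the light source.
#' @return An object of class `spd`.
#' @examples
#' lamp <- spd(380:780, rep(1, 401), name = "equal-energy")
#' peak_wavelength(lamp)
#' @export
spd <- function(wavelengths_nm, intensities, name = "") {
  wavelengths_nm <- as.numeric(wavelengths_nm)
  intensities <- as.numeric(intensities)
  if (length(wavelengths_nm) != length(intensities)) {
    rlang::abort("`wavelengths_nm` and `intensities` must have the same length.",
      class = "bilistrip_error_invalid_spectrum")
  }
  if (length(wavelengths_nm) < 1 || is.unsorted(wavelengths_nm, strictly = TRUE)) {
    rlang::abort("`wavelengths_nm` must be strictly increasing.",
      class = "bilistrip_error_invalid_spectrum")
  }
  if (anyNA(intensities) || any(intensities < 0)) {
    rlang::abort("`intensities` must be non-negative and free of NA.",
      class = "bilistrip_error_invalid_spectrum")
  }
  structure(
    list(wavelengths_nm = wavelengths_nm, intensities = intensities,
         name = as.character(name)),
    class = "spd"
  )
}

#' @export
print.spd <- function(x, ...) {
  rng <- range(x$wavelengths_nm)
  cat(sprintf("<spd> %s: %d samples, %g-%g nm\n",
              if (nzchar(x$name)) x$name else "(unnamed)",
              length(x$wavelengths_nm), rng[1], rng[2]))
  invisible(x)
}

#' @method as_tibble spd
#' @export
as_tibble.spd <- function(x, ...) {
  tibble::tibble(wavelength_nm = x$wavelengths_nm, intensity = x$intensities)
}

#' Reflectance spectra
#'
#' A `reflectance_spectrum` holds the fraction of incident light reflected by
#' the test paper per wavelength, \eqn{R(\lambda)}, with values in \[0, 1\].
#'
#' @param wavelengths_nm Strictly increasing numeric vector (nm).
#' @param reflectance Numeric vector in \[0, 1\], same length.
#' @return An object of class `reflectance_spectrum`.
#' @export
reflectance_spectrum <- function(wavelengths_nm, reflectance) {
  wavelengths_nm <- as.numeric(wavelengths_nm)
  reflectance <- as.numeric(reflectance)
  if (length(wavelengths_nm) != length(reflectance)) {
    rlang::abort("`wavelengths_nm` and `reflectance` must have the same length.",
      class = "bilistrip_error_invalid_spectrum")
  }
  if (length(wavelengths_nm) < 1 || is.unsorted(wavelengths_nm, strictly = TRUE)) {
    rlang::abort("`wavelengths_nm` must be strictly increasing.",
      class = "bilistrip_error_invalid_spectrum")
  }
  if (anyNA(reflectance) || any(reflectance < 0) || any(reflectance > 1)) {
    rlang::abort("`reflectance` must lie in [0, 1].",
      class = "bilistrip_error_invalid_spectrum")
  }
  structure(
    list(wavelengths_nm = wavelengths_nm, reflectance = reflectance),
    class = "reflectance_spectrum"
  )
}

#' @method as_tibble reflectance_spectrum
#' @export
as_tibble.reflectance_spectrum <- function(x, ...) {
  tibble::tibble(wavelength_nm = x$wavelengths_nm, reflectance = x$reflectance)
}

# trapezoidal integral on an (already sorted) grid
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

# asymmetric Gaussian lobe: separate widths left/right of the mode
agauss <- function(lambda, mu, sd_left, sd_right = sd_left) {
  s <- ifelse(lambda < mu, sd_left, sd_right)
  exp(-((lambda - mu)^2) / (2 * s^2))
}

#' Built-in parametric light-source spectra
#'
#' Synthetic spectral power distributions for the three light sources used in
#' test-strip imaging: a deuterium arc lamp (`"d2"`), a halogen lamp (`"h2"`)
#' and a phosphor-converted mini-LED (`"mini_led"`). The shapes are parametric
#' (Gaussian / thermal-like lobes) constrained to the sources' published peak
#' wavelengths, wavelength ranges, and approximate CIE 1931 chromaticities:
#' d2 peaks at 238.8 nm on 190-780 nm (a narrow UV line over a weak bluish
#' continuum), h2 peaks at 583.8 nm on 380-930 nm (a smooth broad thermal
#' curve), and mini_led peaks at 580.4 nm on 380-780 nm (a small blue pump
#' lobe near 450 nm under a dominant yellow phosphor lobe).
#'
#' @param name One of `"d2"`, `"h2"`, `"mini_led"`.
#' @return An [spd].
#' @examples
#' peak_wavelength(spd_preset("mini_led"))
#' @export
spd_preset <- function(name) {
  name <- as.character(name)[1]
  grid_with <- function(from, to, peak) sort(unique(c(seq(from, to, by = 1), peak)))
  switch(name,
    mini_led = {
      wl <- grid_with(380, 780, 580.4)
      i <- 0.60 * agauss(wl, 450, 16) + agauss(wl, 580.4, 60, 70)
      spd(wl, i, name = "mini_led")
    },
    h2 = {
      wl <- grid_with(380, 930, 583.8)
      i <- agauss(wl, 583.8, 93, 230)
      spd(wl, i, name = "h2")
    },
    d2 = {
      wl <- grid_with(190, 780, 238.8)
      i <- agauss(wl, 238.8, 7) + 0.10 * agauss(wl, 420, 55, 90) +
        0.09 * agauss(wl, 650, 50)
      spd(wl, i, name = "d2")
    },
    rlang::abort(
      sprintf("Unknown light-source preset \"%s\" (expected d2, h2 or mini_led).", name),
      class = "bilistrip_error_preset_not_found")
  )
}

#' Wavelength of maximum emission
#'
#' Returns the grid wavelength at which the spectrum attains its maximum
#' intensity. Ties are broken toward the smallest wavelength so the result is
#' deterministic.
#'
#' @param x An [spd].
#' @return Wavelength in nm (scalar).
#' @examples
#' peak_wavelength(spd_preset("h2"))
#' @export
peak_wavelength <- function(x) {
  stopifnot(inherits(x, "spd"))
  if (all(x$intensities <= 0)) {
    rlang::abort("Spectrum has no positive intensity; peak wavelength undefined.",
      class = "bilistrip_error_degenerate_spectrum")
  }
  x$wavelengths_nm[which.max(x$intensities)]
}

# Restrict two spectra to their overlapping wavelength range and resample both
# onto the union of their grid points within it, by linear interpolation.
common_grid <- function(wl1, y1, wl2, y2) {
  lo <- max(min(wl1), min(wl2))
  hi <- min(max(wl1), max(wl2))
  if (lo > hi) {
    rlang::abort("Spectra have disjoint wavelength ranges.",
      class = "bilistrip_error_no_overlap")
  }
  g <- sort(unique(c(wl1, wl2)))
  g <- g[g >= lo & g <= hi]
  resample <- function(wl, y) {
    if (length(wl) >= 2) stats::approx(wl, y, xout = g)$y
    else y[match(g, wl)]
  }
  list(grid = g, y1 = resample(wl1, y1), y2 = resample(wl2, y2))
}

#' Spectrum reflected by the test paper
#'
#' Multiplies the illuminant spectrum \eqn{P(\lambda)} by the paper's
#' reflectance \eqn{R(\lambda)} pointwise, giving the spectrum of the light
#' leaving the reacted test paper. Both inputs are resampled by linear
#' interpolation onto the union of their grids over the overlapping range.
#'
#' @param p An [spd] (the illuminant).
#' @param r A [reflectance_spectrum], or a second [spd] (the product is
#'   commutative in value).
#' @return An [spd] on the common grid.
#' @export
spectral_product <- function(p, r) {
  stopifnot(inherits(p, "spd"))
  ry <- if (inherits(r, "reflectance_spectrum")) r$reflectance
        else if (inherits(r, "spd")) r$intensities
        else rlang::abort("`r` must be a reflectance_spectrum or spd.",
                          class = "bilistrip_error_invalid_spectrum")
  cg <- common_grid(p$wavelengths_nm, p$intensities, r$wavelengths_nm, ry)
  spd(cg$grid, cg$y1 * cg$y2,
      name = if (nzchar(p$name)) paste0(p$name, " x paper") else "")
}

# CIE 1931 2-degree standard-observer colour-matching functions, interpolated
# to a 1 nm grid over 380-780 nm from the packaged 5 nm table.
cie_cmf_1nm <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "cie1931_xyz_2deg_5nm.csv",
                          package = "bilistrip", mustWork = TRUE)
      tab <- utils::read.csv(path)
      g <- seq(380, 780, by = 1)
      cache <<- list(
        wavelength_nm = g,
        xbar = stats::approx(tab$wavelength_nm, tab$xbar, g)$y,
        ybar = stats::approx(tab$wavelength_nm, tab$ybar, g)$y,
        zbar = stats::approx(tab$wavelength_nm, tab$zbar, g)$y
      )
    }
    cache
  }
})

#' Packaged CIE 1931 colour-matching functions
#'
#' Returns the CIE 1931 2-degree standard-observer colour-matching functions
#' shipped with the package, linearly interpolated to a 1 nm grid over
#' 380-780 nm.
#'
#' @return A tibble with columns `wavelength_nm`, `xbar`, `ybar`, `zbar`.
#' @export
cie_cmf <- function() {
  tibble::as_tibble(cie_cmf_1nm())
}

#' CIE 1931 chromaticity of a spectrum
#'
#' Integrates the spectrum against the packaged CIE 1931 2-degree
#' colour-matching functions (trapezoidal rule on a 1 nm grid over
#' 380-780 nm) to obtain tristimulus values \eqn{X, Y, Z}, and returns the
#' chromaticity coordinates \eqn{x = X/(X+Y+Z)}, \eqn{y = Y/(X+Y+Z)}.
#'
#' @param x An [spd] with positive power somewhere in 380-780 nm.
#' @return A one-row tibble with columns `x` and `y`.
#' @examples
#' cie_xy(spd(380:780, rep(1, 401)))
#' @export
cie_xy <- function(x) {
  stopifnot(inherits(x, "spd"))
  cmf <- cie_cmf_1nm()
  g <- cmf$wavelength_nm
  p <- stats::approx(x$wavelengths_nm, x$intensities, xout = g,
                     yleft = 0, yright = 0)$y
  p[is.na(p)] <- 0
  if (all(p <= 0)) {
    rlang::abort("Spectrum has no power in the visible band (380-780 nm).",
      class = "bilistrip_error_degenerate_spectrum")
  }
  X <- trapz(g, p * cmf$xbar)
  Y <- trapz(g, p * cmf$ybar)
  Z <- trapz(g, p * cmf$zbar)
  tibble::tibble(x = X / (X + Y + Z), y = Y / (X + Y + Z))
}

#' Camera spectral response model
#'
#' A three-channel camera model with Gaussian spectral sensitivities. The
#' defaults (channel centres 600/540/460 nm for R/G/B, 60 nm full width at
#' half maximum) stand in for unpublished smartphone sensitivities; only the
#' relative channel behaviour matters for calibration. `exposure_scale` maps
#' the integrated linear signal to the \[0, 1\] range before sRGB encoding.
#'
#' @param centers_nm Channel centres, named or ordered R, G, B (nm).
#' @param fwhm_nm Full width at half maximum of each channel (nm), recycled.
#' @param exposure_scale Positive scalar exposure factor.
#' @return An object of class `camera_response`.
#' @export
camera_response <- function(centers_nm = c(R = 600, G = 540, B = 460),
                            fwhm_nm = 60, exposure_scale = 1) {
  if (!is.numeric(exposure_scale) || length(exposure_scale) != 1 ||
      !is.finite(exposure_scale) || exposure_scale <= 0) {
    rlang::abort("`exposure_scale` must be a positive scalar.",
      class = "bilistrip_error_configuration")
  }
  fwhm_nm <- rep_len(fwhm_nm, 3)
  sd_nm <- fwhm_nm / (2 * sqrt(2 * log(2)))
  wl <- seq(380, 780, by = 1)
  sens <- vapply(1:3, function(k) exp(-((wl - centers_nm[k])^2) / (2 * sd_nm[k]^2)),
                 numeric(length(wl)))
  colnames(sens) <- c("R", "G", "B")
  structure(
    list(wavelengths_nm = wl, sensitivities = sens,
         exposure_scale = exposure_scale),
    class = "camera_response"
  )
}

# sRGB transfer function (IEC 61966-2-1) on linear values in [0, 1]
#' Encode or decode the sRGB transfer function
#'
#' `srgb_encode()` maps linear-light values in \[0, 1\] to nonlinear sRGB
#' values; `srgb_decode()` inverts it. The 256 representable 8-bit channel
#' values round-trip exactly.
#'
#' @param x Numeric vector in \[0, 1\].
#' @return Numeric vector in \[0, 1\].
#' @export
srgb_encode <- function(x) {
  ifelse(x <= 0.0031308, 12.92 * x, 1.055 * x^(1 / 2.4) - 0.055)
}

#' @rdname srgb_encode
#' @export
srgb_decode <- function(x) {
  ifelse(x <= 0.04045, x / 12.92, ((x + 0.055) / 1.055)^2.4)
}

# deterministic round-half-up (base round() rounds half to even)
round_half_up <- function(x) floor(x + 0.5)

#' Render a spectrum to an 8-bit sRGB triple
#'
#' Integrates the spectrum against each camera channel's sensitivity
#' (trapezoidal rule on the camera's 1 nm grid), scales by the camera's
#' exposure factor, clips to \[0, 1\], applies the sRGB transfer function and
#' quantizes to 0-255 (round half up).
#'
#' @param x An [spd].
#' @param cam A [camera_response].
#' @return Named integer vector `c(R =, G =, B =)` in 0-255.
#' @export
spd_to_srgb <- function(x, cam = camera_response()) {
  stopifnot(inherits(x, "spd"), inherits(cam, "camera_response"))
  lin <- linear_channel_signal(x, cam)
  lin <- pmin(pmax(lin * cam$exposure_scale, 0), 1)
  out <- as.integer(round_half_up(255 * srgb_encode(lin)))
  names(out) <- c("R", "G", "B")
  out
}

# per-channel linear signal before exposure scaling/clipping
linear_channel_signal <- function(x, cam) {
  g <- cam$wavelengths_nm
  p <- stats::approx(x$wavelengths_nm, x$intensities, xout = g,
                     yleft = 0, yright = 0)$y
  p[is.na(p)] <- 0
  vapply(1:3, function(k) trapz(g, p * cam$sensitivities[, k]), numeric(1))
}

#' Read or write a spectrum as CSV
#'
#' Spectra are exchanged as two-column CSV files with header
#' `wavelength_nm,value`, rows sorted by ascending wavelength.
#'
#' @param path File path.
#' @param type `"spd"` or `"reflectance"`; controls the returned class.
#' @return For `read_spectrum()`, an [spd] or [reflectance_spectrum].
#' @export
read_spectrum <- function(path, type = c("spd", "reflectance")) {
  type <- match.arg(type)
  tab <- utils::read.csv(path)
  if (!all(c("wavelength_nm", "value") %in% names(tab))) {
    rlang::abort(sprintf("%s: expected columns wavelength_nm,value.", path),
      class = "bilistrip_error_io")
  }
  tab <- tab[order(tab$wavelength_nm), ]
  if (type == "spd") spd(tab$wavelength_nm, tab$value, name = basename(path))
  else reflectance_spectrum(tab$wavelength_nm, tab$value)
}

#' @rdname read_spectrum
#' @param x An [spd] or [reflectance_spectrum] to write.
#' @export
write_spectrum <- function(x, path) {
  value <- if (inherits(x, "spd")) x$intensities else x$reflectance
  utils::write.csv(
    data.frame(wavelength_nm = x$wavelengths_nm, value = value),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
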