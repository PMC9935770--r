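test_that("light-source presets match their published peaks and supports", {
  mini <- spd_preset("mini_led")
  expect_equal(peak_wavelength(mini), 580.4)
  expect_equal(range(mini$wavelengths_nm), c(380, 780))

  h2 <- spd_preset("h2")
  expect_equal(peak_wavelength(h2), 583.8)
  expect_equal(range(h2$wavelengths_nm), c(380, 930))

  d2 <- spd_preset("d2")
  expect_equal(peak_wavelength(d2), 238.8)
  expect_equal(range(d2$wavelengths_nm), c(190, 780))

  expect_error(spd_preset("xenon"), class = "bilistrip_error_preset_not_found")
})

test_that("preset chromaticities sit near the published lamp coordinates", {
  # published (x, y): d2 (0.3250, 0.2694); h2 (0.4042, 0.4137);
  # mini-LED (0.3867, 0.3862). The parametric shapes are only loosely
  # constrained, so the tolerance is wide.
  published <- list(d2 = c(0.3250, 0.2694), h2 = c(0.4042, 0.4137),
                    mini_led = c(0.3867, 0.3862))
  for (nm in names(published)) {
    xy <- cie_xy(spd_preset(nm))
    expect_lt(max(abs(c(xy$x, xy$y) - published[[nm]])), 0.05)
  }
})

test_that("peak_wavelength handles single bins, ties and degenerate input", {
  single <- spd(c(400, 500, 600), c(0, 3, 0))
  expect_equal(peak_wavelength(single), 500)

  flat <- spd(380:780, rep(1, 401))
  expect_equal(peak_wavelength(flat), 380)  # tie broken to smallest wavelength

  expect_error(peak_wavelength(spd(380:780, rep(0, 401))),
               class = "bilistrip_error_degenerate_spectrum")
})

test_that("spectral_product behaves as a pointwise product", {
  p <- spd_preset("mini_led")
  ones <- reflectance_spectrum(c(300, 1000), c(1, 1))
  expect_equal(spectral_product(p, ones)$intensities, p$intensities)
  expect_equal(peak_wavelength(spectral_product(p, ones)), peak_wavelength(p))

  zeros <- reflectance_spectrum(c(300, 1000), c(0, 0))
  expect_true(all(spectral_product(p, zeros)$intensities == 0))

  one_bin <- spd(550, 2.0)
  half <- reflectance_spectrum(c(500, 600), c(0.5, 0.5))
  prod <- spectral_product(one_bin, half)
  expect_equal(prod$wavelengths_nm, 550)
  expect_equal(prod$intensities, 1.0)

  expect_error(
    spectral_product(spd(400:500, rep(1, 101)),
                     reflectance_spectrum(600:700, rep(1, 101))),
    class = "bilistrip_error_no_overlap")
})

test_that("spectral_product is commutative and never amplifies", {
  set.seed(42)
  for (i in 1:20) {
    wl <- sort(sample(380:780, 30))
    p <- spd(wl, runif(30))
    r <- reflectance_spectrum(sort(sample(350:800, 25)), runif(25))
    pr <- spectral_product(p, r)
    rp <- spectral_product(spd(r$wavelengths_nm, r$reflectance),
                           spd(p$wavelengths_nm, p$intensities))
    expect_equal(pr$intensities, rp$intensities)
    p_on_grid <- approx(p$wavelengths_nm, p$intensities, pr$wavelengths_nm)$y
    expect_true(all(pr$intensities <= p_on_grid + 1e-12))
  }
})

test_that("chromaticity integrates correctly against the packaged CMF table", {
  ee <- cie_xy(spd(380:780, rep(1, 401)))
  expect_lt(abs(ee$x - 1 / 3), 2e-3)
  expect_lt(abs(ee$y - 1 / 3), 2e-3)

  # narrow triangular line at 550 nm: (x, y) must equal the CMF row ratios
  cmf <- cie_cmf()
  row <- cmf[cmf$wavelength_nm == 550, ]
  tot <- row$xbar + row$ybar + row$zbar
  mono <- cie_xy(spd(c(549, 550, 551), c(0, 1, 0)))
  expect_equal(mono$x, row$xbar / tot, tolerance = 1e-10)
  expect_equal(mono$y, row$ybar / tot, tolerance = 1e-10)

  expect_error(cie_xy(spd(380:780, rep(0, 401))),
               class = "bilistrip_error_degenerate_spectrum")
  # UV-only power is invisible to the standard observer
  expect_error(cie_xy(spd(200:300, rep(1, 101))),
               class = "bilistrip_error_degenerate_spectrum")
})

test_that("chromaticities of random spectra stay inside the unit simplex", {
  set.seed(7)
  for (i in 1:25) {
    s <- spd(380:780, runif(401))
    xy <- cie_xy(s)
    expect_gte(xy$x, 0)
    expect_gt(xy$y, 0)
    expect_lte(xy$x + xy$y, 1)
  }
})

test_that("sRGB transfer function round-trips all 256 channel codes", {
  codes <- 0:255
  back <- round(255 * srgb_encode(srgb_decode(codes / 255)))
  expect_identical(as.integer(back), codes)
})

test_that("spd_to_srgb renders by clipped, encoded channel integrals", {
  cam <- camera_response(exposure_scale = 1)
  expect_identical(unname(spd_to_srgb(spd(380:780, rep(0, 401)), cam)),
                   c(0L, 0L, 0L))

  # doubling the spectrum doubles the linear signal (checked through the
  # decoded digital values while all channels stay below clipping)
  s1 <- spd(380:780, rep(1e-4, 401))
  s2 <- spd(380:780, rep(2e-4, 401))
  lin1 <- srgb_decode(spd_to_srgb(s1, cam) / 255)
  lin2 <- srgb_decode(spd_to_srgb(s2, cam) / 255)
  expect_equal(lin2, 2 * lin1, tolerance = 0.02)

  expect_error(camera_response(exposure_scale = 0),
               class = "bilistrip_error_configuration")
  expect_error(camera_response(exposure_scale = -1),
               class = "bilistrip_error_configuration")
})

test_that("spectrum CSV files round-trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  s <- spd_preset("mini_led")
  write_spectrum(s, path)
  s2 <- read_spectrum(path, "spd")
  expect_equal(s2$wavelengths_nm, s$wavelengths_nm)
  expect_equal(s2$intensities, s$intensities)

  r <- reflectance_spectrum(400:500, seq(0, 1, length.out = 101))
  write_spectrum(r, path)
  r2 <- read_spectrum(path, "reflectance")
  expect_equal(r2$reflectance, r$reflectance)
})
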