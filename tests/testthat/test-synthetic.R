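test_that("the default concentration series spans 0.1-2.0 mg/dL in 12 steps", {
  concs <- default_concentration_series()
  expect_length(concs, 12)
  expect_equal(concs[1], 0.1)
  expect_equal(concs[12], 2.0)
  expect_true(all(diff(concs) > 0))
  expect_equal(unique(round(diff(concs), 12)), round(19 / 110, 12))
})

test_that("mean_gray evaluates the preset line with clipping", {
  g <- response_preset("mini_led", "G")
  expect_equal(mean_gray(0, g), 221.81)
  expect_equal(mean_gray(1.0, g), 215.5129)
  # far beyond the calibrated range the line clips at zero
  expect_equal(mean_gray(1000, g), 0)
  expect_error(mean_gray(-0.1, g), class = "bilistrip_error_domain")
})

test_that("response presets carry the published green-channel lines", {
  tab <- response_presets()
  g <- tab[tab$channel == "G", ]
  expect_equal(g$slope[match(c("mini_led", "h2", "d2"), g$light_source)],
               c(-6.2971, -6.2029, -1.8078))
  expect_equal(g$intercept[match(c("mini_led", "h2", "d2"), g$light_source)],
               c(221.81, 221.72, 231.56))
  expect_true(all(tab$slope < 0))
  expect_true(all(tab$intercept >= 0 & tab$intercept <= 255))
  expect_error(response_preset("d2", "G", sigma = "lod"),
               class = "bilistrip_error_preset_not_found")
})

test_that("calibration tables are reproducible and exact when noiseless", {
  concs <- default_concentration_series()
  g <- response_preset("mini_led", "G")

  quiet <- generate_calibration_table(concs, g, sigma = 0, seed = 1)
  expect_equal(quiet$mean_G, mean_gray(concs, g))
  one <- generate_calibration_table(c(0, 1, 2), g, sigma = 0)
  expect_equal(one$mean_G[2], 215.5129)

  t1 <- generate_calibration_table(concs, g, seed = 123)
  t2 <- generate_calibration_table(concs, g, seed = 123)
  expect_identical(t1, t2)

  expect_error(generate_calibration_table(concs, g, sigma = -1),
               class = "bilistrip_error_configuration")
  expect_error(generate_calibration_table(numeric(0), g),
               class = "bilistrip_error_domain")
})

test_that("noiseless tables are fit back to the generating line", {
  concs <- default_concentration_series()
  for (ls in c("mini_led", "h2", "d2")) {
    p <- response_preset(ls, "G")
    fit <- fit_line(generate_calibration_table(concs, p, sigma = 0), "G")
    expect_equal(fit$slope, p$slope, tolerance = 1e-9)
    expect_equal(fit$intercept, p$intercept, tolerance = 1e-9)
    expect_equal(fit$r_squared, 1.0, tolerance = 1e-12)
  }
})

test_that("shared-noise strip responses are deterministic and three-channel", {
  concs <- default_concentration_series()
  a <- generate_strip_responses(concs, "h2", seed = 5)
  b <- generate_strip_responses(concs, "h2", seed = 5)
  expect_identical(a, b)
  expect_named(a, c("concentration_mg_dl", "mean_R", "mean_G", "mean_B"))
  expect_equal(attr(a, "light_source"), "h2")
})

test_that("biliverdin reflectance follows Beer-Lambert behaviour", {
  r0 <- biliverdin_reflectance(0, absorbance_scale = 0.5)
  expect_true(all(r0$reflectance == 0.92))

  concs <- c(0.2, 0.5, 1.0, 2.0)
  prev <- r0$reflectance
  for (cc in concs) {
    r <- biliverdin_reflectance(cc, absorbance_scale = 0.5)
    expect_true(all(r$reflectance <= prev + 1e-12))
    prev <- r$reflectance
  }
  expect_error(biliverdin_reflectance(-1), class = "bilistrip_error_domain")
})

test_that("rendered green means decrease over the concentration series", {
  g_means <- vapply(default_concentration_series(), function(cc) {
    img <- render_strip_image(cc, "mini_led", noise_sd = 0, size_px = 64,
                              diameter_px = 50)
    mask <- circular_roi_mask(50, 50, origin = c(7, 7))
    channel_stats(img, mask)$mean_G
  }, numeric(1))
  expect_true(all(diff(g_means) < 0))
})

test_that("noiseless spectral renders track the green calibration line", {
  p <- response_preset("mini_led", "G")
  mask <- circular_roi_mask(130, 130, origin = c(5, 5))
  for (cc in c(0, 0.27, 0.62, 1.0)) {
    img <- render_strip_image(cc, "mini_led", noise_sd = 0)
    st <- channel_stats(img, mask)
    expect_lt(abs(st$mean_G - mean_gray(cc, p)), 2)
  }
})

test_that("strip rendering is geometry-checked, seeded and file-stable", {
  expect_error(render_strip_image(0.5, "mini_led", size_px = 100,
                                  diameter_px = 130),
               class = "bilistrip_error_geometry")

  img <- render_strip_image(0.5, "mini_led", noise_sd = 0, size_px = 64,
                            diameter_px = 40)
  corner <- img$pixels[1:5, 1:5, ]
  expect_true(all(corner[, , 1] == 30 & corner[, , 2] == 30 & corner[, , 3] == 30))

  a <- render_strip_image(0.5, "mini_led", noise_sd = 2, size_px = 64,
                          diameter_px = 40, seed = 99)
  b <- render_strip_image(0.5, "mini_led", noise_sd = 2, size_px = 64,
                          diameter_px = 40, seed = 99)
  expect_identical(a$pixels, b$pixels)

  fa <- withr::local_tempfile(fileext = ".png")
  fb <- withr::local_tempfile(fileext = ".png")
  write_strip_png(a, fa, sidecar = FALSE)
  write_strip_png(b, fb, sidecar = FALSE)
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fb, "raw", file.size(fb)))
})

test_that("strip images round-trip through PNG with their sidecar metadata", {
  img <- render_strip_image(0.73, "h2", noise_sd = 1, size_px = 48,
                            diameter_px = 32, seed = 4)
  path <- file.path(withr::local_tempdir(), "strip.png")
  write_strip_png(img, path)
  back <- read_strip_image(path)
  expect_identical(back$pixels, img$pixels)
  expect_equal(back$light_source, "h2")
  expect_equal(back$concentration_mg_dl, 0.73)
})
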