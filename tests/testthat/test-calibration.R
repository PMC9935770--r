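test_that("a hand-worked OLS example is reproduced exactly", {
  # c = (0, 1, 2), Y = (0, 1, 1): slope 1/2, intercept 1/6, SSR = 1/2,
  # SST = 2/3, R^2 = 3/4, SSE = 1/6
  ds <- tibble::tibble(concentration_mg_dl = c(0, 1, 2), mean_G = c(0, 1, 1))
  fit <- fit_line(ds, "G")
  expect_equal(fit$slope, 0.5, tolerance = 1e-12)
  expect_equal(fit$intercept, 1 / 6, tolerance = 1e-12)
  expect_equal(fit$r_squared, 0.75, tolerance = 1e-12)
  expect_equal(fit$residual_sd, sqrt(1 / 6), tolerance = 1e-12)
})

test_that("fits interpolate exact lines and reject degenerate designs", {
  ds <- tibble::tibble(concentration_mg_dl = c(0, 0, 2),
                       mean_G = c(5, 5, 11))
  fit <- fit_line(ds, "G")
  expect_equal(fit$slope, 3, tolerance = 1e-12)
  expect_equal(fit$intercept, 5, tolerance = 1e-12)

  expect_error(
    fit_line(tibble::tibble(concentration_mg_dl = c(1, 1, 1),
                            mean_G = c(1, 2, 3)), "G"),
    class = "bilistrip_error_singular_design")
  expect_error(
    fit_line(tibble::tibble(concentration_mg_dl = c(0, 1),
                            mean_G = c(1, 2)), "G"),
    class = "bilistrip_error_insufficient_data")
  expect_error(
    fit_line(tibble::tibble(concentration_mg_dl = 1:5, other = 1:5), "G"),
    class = "bilistrip_error_invalid_dataset")
})

test_that("the regression-sum R-squared equals 1 - SSE/SST on random data", {
  set.seed(2024)
  for (i in 1:50) {
    n <- sample(3:30, 1)
    x <- round(runif(n, 0, 2), 3)
    if (length(unique(x)) < 2) next
    y <- 200 - 6 * x + rnorm(n, 0, runif(1, 0.1, 10))
    ds <- tibble::tibble(concentration_mg_dl = x, mean_G = y)
    fit <- fit_line(ds, "G")
    oracle <- ols_oracle(x, y)
    expect_equal(fit$r_squared, oracle$r2_ssr, tolerance = 1e-10)
    expect_equal(fit$r_squared, oracle$r2_sse, tolerance = 1e-10)
    expect_equal(fit$slope, oracle$slope, tolerance = 1e-10)
    expect_gte(fit$r_squared, 0)
    expect_lte(fit$r_squared, 1 + 1e-12)
  }
})

test_that("R-squared is invariant under affine response rescaling", {
  set.seed(9)
  x <- default_concentration_series()
  y <- 220 - 6 * x + rnorm(12, 0, 1.2)
  base <- fit_line(tibble::tibble(concentration_mg_dl = x, mean_G = y), "G")
  for (ab in list(c(2, 0), c(-1.5, 10), c(0.01, 100))) {
    fit <- fit_line(tibble::tibble(concentration_mg_dl = x,
                                   mean_G = ab[1] * y + ab[2]), "G")
    expect_equal(fit$r_squared, base$r_squared, tolerance = 1e-10)
  }
})

test_that("slope estimates are unbiased at the packaged noise levels", {
  concs <- default_concentration_series()
  for (ls in c("mini_led", "h2", "d2")) {
    p <- response_preset(ls, "G")
    slopes <- vapply(1:500, function(s) {
      fit_line(generate_calibration_table(concs, p, seed = 20000 + s), "G")$slope
    }, numeric(1))
    expect_lt(abs(mean(slopes) - p$slope) / abs(p$slope), 0.02)
  }
})

test_that("channels are ranked by descending R-squared with R,G,B tie order", {
  fits <- list()
  for (ls in c("d2", "h2", "mini_led")) {
    ds <- generate_strip_responses(default_concentration_series(), ls,
                                   seed = 31)
    for (ch in c("R", "G", "B")) fits[[paste(ls, ch)]] <- fit_line(ds, ch)
  }
  ranked <- rank_channels(fits)
  top <- ranked[ranked$rank == 1, ]
  expect_true(all(top$channel == "G"))

  single <- rank_channels(fits[["d2 B"]])
  expect_equal(single$rank, 1)

  # identical fits tie; R sorts before G
  ds <- tibble::tibble(concentration_mg_dl = c(0, 1, 2, 3),
                       mean_R = c(1, 2, 3.1, 4), mean_G = c(1, 2, 3.1, 4))
  tie <- rank_channels(list(fit_line(ds, "G"), fit_line(ds, "R")))
  expect_equal(tie$channel[tie$rank == 1], "R")
})

test_that("tidy and glance views expose the fit as tibbles", {
  ds <- generate_calibration_table(default_concentration_series(),
                                   response_preset("h2", "G"), seed = 3)
  fit <- fit_line(ds, "G")
  td <- tidy(fit)
  expect_equal(td$term, c("intercept", "slope"))
  expect_equal(td$estimate, c(fit$intercept, fit$slope))
  gl <- glance(fit)
  expect_equal(gl$r_squared, fit$r_squared)
  expect_equal(gl$light_source, "h2")
  expect_equal(gl$n, 12L)
})

test_that("calibration datasets round-trip through CSV", {
  ds <- generate_strip_responses(default_concentration_series(), "mini_led",
                                 seed = 17)
  path <- withr::local_tempfile(fileext = ".csv")
  write_calibration_csv(ds, path)
  back <- read_calibration_csv(path)
  expect_equal(back$mean_G, ds$mean_G)
  expect_equal(attr(back, "light_source"), "mini_led")
  expect_equal(fit_line(back, "G")$r_squared, fit_line(ds, "G")$r_squared)
})
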