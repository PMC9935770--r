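Package: bilistrip
Title: Colorimetric Quantification of Direct Bilirubin from Test-Strip Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying direct (conjugated) bilirubin from smartphone
    photographs of colorimetric urine test papers. Models the light source's
    spectral power distribution and the biliverdin-stained paper's reflectance,
    renders spectra to 8-bit sRGB through a camera response model, extracts
    circular regions of interest from strip images, computes per-channel mean
    grayscale values, fits linear calibration curves with the
    regression-sum-of-squares coefficient of determination, and derives limits
    of detection and quantification from calibration residuals. Includes a
    seeded synthetic test-strip generator emulating 12-point calibration series
    under deuterium, halogen and mini-LED illumination, and an end-to-end
    pipeline from an image manifest to a per-light-source comparison report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
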