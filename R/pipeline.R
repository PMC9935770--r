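#' Read an image manifest
#'
#' The manifest is a CSV with columns `filename`, `concentration_mg_dl`,
#' `light_source`. Relative filenames are resolved against the manifest's
#' directory.
#'
#' @param path Manifest CSV path.
#' @return A tibble with the three columns plus `path` (resolved file
#'   path).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("Manifest not found: %s", path),
      class = "bilistrip_error_io")
  }
  tab <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("filename", "concentration_mg_dl", "light_source")
  if (!all(need %in% names(tab))) {
    rlang::abort(sprintf("Manifest must have columns %s.",
                         paste(need, collapse = ", ")),
      class = "bilistrip_error_io")
  }
  if (nrow(tab) == 0) {
    rlang::abort("Manifest is empty.", class = "bilistrip_error_usage")
  }
  base <- dirname(normalizePath(path))
  tab$path <- ifelse(grepl("^(/|[A-Za-z]:)", tab$filename), tab$filename,
                     file.path(base, tab$filename))
  tab
}

pipeline_log <- function(verbose, fmt, ...) {
  if (verbose) {
    message(sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    sprintf(fmt, ...)))
  }
}

#' Run the image-to-report analysis pipeline
#'
#' End-to-end workflow: each manifest image is loaded, the circular region
#' of interest is extracted, and per-channel mean grayscales are computed;
#' the per-image means are assembled into one calibration dataset per light
#' source; each channel's calibration line is fitted by ordinary least
#' squares with the regression-sum-of-squares \eqn{R^2}; channels are
#' ranked by linearity; and detection/quantification limits are derived
#' from the best channel's residual standard deviation. Unreadable images
#' are logged, counted and skipped without aborting the run.
#'
#' @param manifest A manifest tibble from [read_manifest()], or a manifest
#'   CSV path.
#' @param out_dir Optional output directory; when given, writes
#'   `image_stats.csv`, `fits.csv`, `fits.json`, `comparison.csv` and
#'   `run.log`.
#' @param roi_side ROI window side, px.
#' @param roi_diameter ROI disc diameter, px.
#' @param channels Channels to fit.
#' @param lod_convention Detection-limit convention tag.
#' @param verbose Log progress to standard error.
#' @return An object of class `strip_report`: a list with tibbles
#'   `image_stats`, `fits`, `ranking`, `comparison`, `limits` and
#'   `failures`.
#' @export
run_pipeline <- function(manifest, out_dir = NULL, roi_side = 130,
                         roi_diameter = 130, channels = c("R", "G", "B"),
                         lod_convention = "3sigma/10sigma",
                         verbose = FALSE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (nrow(manifest) == 0) {
    rlang::abort("Manifest is empty.", class = "bilistrip_error_usage")
  }
  if (nrow(manifest) < 3 ||
      length(unique(manifest$concentration_mg_dl)) < 2) {
    rlang::abort(
      "Manifest must reference at least 3 images at 2 distinct concentrations.",
      class = "bilistrip_error_usage")
  }

  failures <- tibble::tibble(filename = character(), error = character())
  stats_rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    res <- tryCatch({
      img <- read_strip_image(row$path)
      h <- dim(img$pixels)[1]; w <- dim(img$pixels)[2]
      mask <- circular_roi_mask(roi_side, roi_diameter,
                                origin = c(floor((h - roi_side) / 2),
                                           floor((w - roi_side) / 2)))
      st <- channel_stats(img, mask)
      st$filename <- row$filename
      st$concentration_mg_dl <- row$concentration_mg_dl
      st$light_source <- row$light_source
      st
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rlang::warn(sprintf("Skipping %s: %s", row$filename,
                          conditionMessage(res)))
      failures <- dplyr::bind_rows(failures,
        tibble::tibble(filename = row$filename,
                       error = conditionMessage(res)))
    } else {
      pipeline_log(verbose, "analyzed %s (%s, %.4g mg/dL)", row$filename,
                   row$light_source, row$concentration_mg_dl)
      stats_rows[[i]] <- res
    }
  }
  image_stats <- dplyr::bind_rows(stats_rows)
  if (nrow(image_stats) == 0) {
    rlang::abort("No manifest image could be analyzed.",
      class = "bilistrip_error_usage")
  }

  fits <- list()
  for (light in unique(image_stats$light_source)) {
    ds <- image_stats[image_stats$light_source == light, ]
    attr(ds, "light_source") <- light
    for (ch in channels) {
      fits[[paste(light, ch)]] <- fit_line(ds, ch)
    }
  }
  ranking <- rank_channels(fits)

  limits <- ranking |>
    dplyr::filter(.data$rank == 1) |>
    dplyr::group_by(.data$light_source) |>
    dplyr::reframe(
      channel = .data$channel,
      detection_limits(.data$slope, .data$residual_sd,
                       convention = lod_convention))

  comparison <- ranking |>
    dplyr::select("light_source", "channel", "r_squared") |>
    tidyr::pivot_wider(names_from = "channel", values_from = "r_squared",
                       names_prefix = "r_squared_") |>
    dplyr::left_join(
      dplyr::select(limits, "light_source", best_channel = "channel",
                    "lod_mg_dl", "loq_mg_dl"),
      by = "light_source") |>
    dplyr::left_join(
      image_stats |>
        dplyr::group_by(.data$light_source) |>
        dplyr::summarise(n_images = dplyr::n(),
                         analysis_points = .data$n_pixels[1]),
      by = "light_source")

  report <- structure(
    list(image_stats = image_stats,
         fits = purrr::map_dfr(fits, glance),
         ranking = ranking, comparison = comparison, limits = limits,
         failures = failures,
         roi = list(side = roi_side, diameter = roi_diameter,
                    total_points = roi_side^2)),
    class = "strip_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.strip_report <- function(x, ...) {
  cat(sprintf("<strip_report> %d images, %d light source(s), %d failed\n",
              nrow(x$image_stats), length(unique(x$image_stats$light_source)),
              nrow(x$failures)))
  print(x$comparison)
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' @param report A `strip_report`.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "strip_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(report$image_stats),
                   file.path(out_dir, "image_stats.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$ranking),
                   file.path(out_dir, "fits.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(fits = report$ranking, limits = report$limits,
         comparison = report$comparison, roi = report$roi),
    file.path(out_dir, "fits.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  utils::write.csv(as.data.frame(report$comparison),
                   file.path(out_dir, "comparison.csv"), row.names = FALSE)
  log_lines <- c(
    sprintf("images analyzed: %d", nrow(report$image_stats)),
    sprintf("images failed: %d", nrow(report$failures)),
    if (nrow(report$failures) > 0)
      sprintf("  failed: %s (%s)", report$failures$filename,
              report$failures$error),
    sprintf("roi: side %d px, diameter %d px, %d total points",
            report$roi$side, report$roi$diameter, report$roi$total_points))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' Generate the synthetic fixture image set
#'
#' Writes one strip PNG (plus JSON sidecar) per light source and
#' concentration - by default 3 light sources times the 12-point series,
#' 36 images - and a manifest CSV (`filename`, `concentration_mg_dl`,
#' `light_source`) consumable by [run_pipeline()]. Disc colours follow the
#' packaged per-channel response lines with strip-level noise shared across
#' channels (see [generate_strip_responses()]) plus per-pixel dither noise.
#' Regenerating with the same seed reproduces byte-identical files.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed driving all randomness.
#' @param light_sources Light sources to simulate.
#' @param concentrations Concentration series, mg/dL.
#' @param noise_sd Per-pixel noise SD, counts.
#' @param size_px Image side, px.
#' @param diameter_px Disc diameter, px.
#' @return The manifest tibble, invisibly, with attribute `path` giving the
#'   manifest CSV location.
#' @export
make_fixtures <- function(out_dir, seed = 1,
                          light_sources = c("d2", "h2", "mini_led"),
                          concentrations = default_concentration_series(),
                          noise_sd = 2, size_px = 140, diameter_px = 130) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, mode = 2) != 0) {
    rlang::abort(sprintf("Output directory is not writable: %s", out_dir),
      class = "bilistrip_error_io")
  }
  rows <- withr::with_seed(seed, {
    purrr::map(light_sources, function(light) {
      eps <- stats::rnorm(length(concentrations))
      purrr::imap(concentrations, function(conc, i) {
        img <- render_preset_strip(conc, light, eps = eps[i],
                                   noise_sd = noise_sd, size_px = size_px,
                                   diameter_px = diameter_px)
        img$seed <- as.integer(seed)
        fn <- sprintf("%s_%02d_%.4f.png", light, i, conc)
        write_strip_png(img, file.path(out_dir, fn))
        tibble::tibble(filename = fn, concentration_mg_dl = conc,
                       light_source = light)
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  })
  manifest_path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(as.data.frame(rows), manifest_path, row.names = FALSE,
                   quote = FALSE)
  attr(rows, "path") <- manifest_path
  invisible(rows)
}

#' Read a pipeline run configuration
#'
#' Run configurations are stored as a flat `key: value` text file (YAML
#' scalars). Recognized keys mirror the command-line flags: `manifest`,
#' `out`, `seed`, `roi_side`, `roi_diameter`, `channel`, `lod_convention`,
#' `verbose`; unknown keys (for example rig metadata such as
#' `camera_distance_cm` or `source_distance_cm`) are carried through
#' untouched.
#'
#' @param path Configuration file path.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("Config file not found: %s", path),
      class = "bilistrip_error_io")
  }
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) {
    rlang::abort(sprintf("%s: expected key: value pairs.", path),
      class = "bilistrip_error_io")
  }
  cfg
}
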