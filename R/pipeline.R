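#' Simulate a synthetic screening dataset on disk
#'
#' Thin orchestration over [generate_experiment()] with the package's
#' default study design: the 7-compound 96-well panel, one frame every
#' 4 minutes for 10 hours, and the default calibration and rendering
#' settings. A `metadata.json` in the output directory records the seed and
#' every tunable.
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param force Overwrite a non-empty output directory.
#' @param ... Passed through to [generate_experiment()] (e.g. `layout`,
#'   `models`, `cfg`, `times`).
#' @return The `synthetic_screen` object, invisibly.
#' @export
run_simulate <- function(out_dir, seed = 1L, force = FALSE, ...) {
  if (missing(out_dir) || is.null(out_dir)) {
    stop_spheroscreen("an output directory is required", "spheroscreen_usage_error")
  }
  generate_experiment(dir = out_dir, seed = seed, overwrite = force, ...)
}

#' Analyze a plate-image dataset end to end
#'
#' Reads the manifest, layout and calibration, measures every well in every
#' frame, computes windowed contraction rates, normalizes them to
#' solvent-matched vehicle controls, and writes `measurements.csv`,
#' `rates.csv` and `report.csv` (plus `tukey.csv` with the
#' compound-vs-vehicle post hoc comparisons and `quality.csv` with the
#' Z'-factor when positive-control wells exist) into `out_dir`. Per-well
#' exclusions are warnings; validation failures are errors.
#'
#' @param images_dir Directory containing the frames and (by default) the
#'   `manifest.csv`, `layout.csv` and `calibration.toml` files.
#' @param out_dir Output directory for result tables (created if needed).
#' @param manifest,layout,calibration Optional explicit paths overriding the
#'   defaults inside `images_dir`.
#' @param window_min Endpoint window (minutes, default 150).
#' @param alpha Significance level (default 0.05).
#' @param seg Optional [seg_config()].
#' @return Invisibly, a list with `measurements`, `rates`, `report`,
#'   `quality` (NULL without positive controls) and the output paths.
#' @export
run_analyze <- function(images_dir, out_dir,
                        manifest = file.path(images_dir, "manifest.csv"),
                        layout = file.path(images_dir, "layout.csv"),
                        calibration = file.path(images_dir, "calibration.toml"),
                        window_min = 150, alpha = 0.05, seg = seg_config()) {
  man <- read_manifest(manifest, image_dir = images_dir)
  lay <- read_plate_layout(layout)
  calib <- read_calibration(calibration)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  measurements <- measure_plate(man, lay, calib, seg)
  write_measurements(measurements, file.path(out_dir, "measurements.csv"))

  rates <- contraction_rates(measurements, lay, window_min = window_min)
  rates <- normalize_rates(rates, lay)
  write_rates(rates, file.path(out_dir, "rates.csv"))

  report <- screen_report(rates, alpha = alpha)
  flat <- dplyr::select(report, -"fit", -"tukey")
  readr::write_csv(flat, file.path(out_dir, "report.csv"), na = "")
  tukey <- dplyr::bind_rows(setNames(report$tukey, report$compound), .id = "compound")
  if (nrow(tukey) > 0) readr::write_csv(tukey, file.path(out_dir, "tukey.csv"))

  quality <- NULL
  if (any(rates$role == "positive_control")) {
    quality <- assay_quality(rates)
    readr::write_csv(quality, file.path(out_dir, "quality.csv"))
  }

  invisible(list(measurements = measurements, rates = rates, report = report,
                 quality = quality, out_dir = out_dir))
}
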