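#' Contraction models for the default screen panel
#'
#' One [contraction_model] per compound in the panel, sharing the base
#' kinetics (`A0`, `A_inf`, `k_top`) and differing only in dose parameters:
#' the nominal IC50 sets `log_ic50`, and the flat negative control gets
#' `k_bot = k_top` (no dose effect).
#'
#' @param compounds Panel tibble from [screen_compounds()].
#' @param base A [contraction_model] providing `A0`, `A_inf`, `k_top`,
#'   `slope_s` shared by every compound.
#' @return Named list of [contraction_model] objects.
#' @export
default_screen_models <- function(compounds = screen_compounds(),
                                  base = contraction_model()) {
  models <- purrr::map2(compounds$ic50_uM, compounds$flat, function(ic50, flat) {
    if (flat) {
      contraction_model(A0 = base$A0, A_inf = base$A_inf, k_top = base$k_top,
                        k_bot = base$k_top, log_ic50 = 0, slope_s = base$slope_s)
    } else {
      contraction_model(A0 = base$A0, A_inf = base$A_inf, k_top = base$k_top,
                        k_bot = 0, log_ic50 = log10(ic50), slope_s = base$slope_s)
    }
  })
  setNames(models, compounds$compound)
}

#' Default acquisition schedule: one frame every 4 minutes for 10 hours
#'
#' @return Times in minutes, `0, 4, ..., 600` (151 frames).
#' @export
default_schedule <- function() seq(0, 600, by = 4)

# true per-well areas (mm^2) at a single time point
well_areas_at <- function(layout, models, vehicle_model, time) {
  active <- layout[layout$role != "empty", ]
  a <- vapply(seq_len(nrow(active)), function(i) {
    cmp <- active$compound[i]
    if (active$role[i] == "vehicle" || is.na(cmp) || !cmp %in% names(models)) {
      area_trajectory(vehicle_model, 0, time)
    } else {
      area_trajectory(models[[cmp]], active$concentration_uM[i], time)
    }
  }, numeric(1))
  setNames(a, active$well)
}

#' Generate a ground-truthed synthetic plate experiment
#'
#' Simulates a full time-lapse toxicity experiment: per-well projected-area
#' trajectories from the contraction models, one rendered plate image per
#' scheduled time, plus the manifest, layout, calibration and ground-truth
#' tables that make the dataset self-contained. All randomness (well-center
#' jitter, per-frame noise) derives from the single `seed`, so identical
#' calls reproduce identical files bit for bit.
#'
#' Ground truth records, per well, the true secant contraction rate over the
#' endpoint window, `(A(0) - A(window)) / window` (mm^2/min, positive for a
#' contracting spheroid), and its value normalized to the mean of the
#' solvent-matched vehicle wells; and per compound the true IC50 (NA for a
#' compound with no dose effect).
#'
#' @param dir Output directory (created; must be empty unless
#'   `overwrite = TRUE`).
#' @param layout A [plate_layout]; must contain at least one vehicle well.
#' @param models Named list of [contraction_model]s, one per compound.
#' @param vehicle_model Model whose zero-dose trajectory vehicle wells follow
#'   (default: shared base kinetics).
#' @param calib A [plate_calibration].
#' @param cfg A [render_config]; its `seed` field is overridden by a stream
#'   derived from `seed`.
#' @param times Acquisition schedule in minutes, strictly increasing.
#' @param window_min Endpoint window used for the ground-truth secant rate.
#' @param seed Master integer seed.
#' @param overwrite Allow writing into a non-empty directory.
#' @param write_images Set `FALSE` to skip image rendering and only produce
#'   tables (useful for kinetics-only consistency checks).
#' @return Invisibly, a list of class `synthetic_screen` with elements `dir`,
#'   `manifest`, `layout`, `calib`, `cfg`, `times`, `ground_truth` (per-well
#'   tibble), `compounds` (per-compound tibble with `true_ic50_uM`),
#'   `window_min`, `seed`.
#' @export
generate_experiment <- function(dir,
                                layout = default_screen_layout(),
                                models = default_screen_models(),
                                vehicle_model = contraction_model(),
                                calib = default_calibration(),
                                cfg = render_config(),
                                times = default_schedule(),
                                window_min = 150,
                                seed = 1L,
                                overwrite = FALSE,
                                write_images = TRUE) {
  stopifnot(inherits(layout, "plate_layout"), inherits(calib, "plate_calibration"),
            inherits(cfg, "render_config"))
  times <- as.numeric(times)
  if (length(times) < 1 || any(!is.finite(times)) || any(times < 0) ||
      (length(times) > 1 && any(diff(times) <= 0))) {
    stop_spheroscreen("times must be non-negative and strictly increasing",
                      "spheroscreen_validation_error")
  }
  if (!any(layout$role == "vehicle")) {
    stop_spheroscreen("layout has no vehicle wells; normalization would be impossible",
                      "spheroscreen_generation_error")
  }
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite) {
    stop_spheroscreen(sprintf("output directory %s is not empty (use overwrite = TRUE)", dir),
                      "spheroscreen_io_error")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  seeds <- derive_seeds(seed, length(times) + 1L)
  cfg$seed <- seeds[1]
  frame_seeds <- seeds[-1]

  # ground truth -------------------------------------------------------------
  active <- as_tibble(layout)[layout$role != "empty", ]
  a0 <- well_areas_at(layout, models, vehicle_model, 0)
  aw <- well_areas_at(layout, models, vehicle_model, window_min)
  gt <- dplyr::mutate(
    dplyr::select(active, "well", "compound", "concentration_uM", "role",
                  "replicate", "solvent"),
    area0_mm2 = unname(a0[.data$well]),
    area_window_mm2 = unname(aw[.data$well]),
    true_rate = (.data$area0_mm2 - .data$area_window_mm2) / window_min
  )
  gt <- dplyr::ungroup(dplyr::mutate(
    dplyr::group_by(gt, .data$solvent),
    true_normalized_rate = .data$true_rate /
      mean(.data$true_rate[.data$role == "vehicle"])
  ))

  compounds <- dplyr::distinct(
    gt[gt$role %in% c("treatment", "positive_control", "negative_control") &
         !is.na(gt$compound), ], .data$compound
  )
  compounds$true_ic50_uM <- vapply(compounds$compound, function(cmp) {
    m <- models[[cmp]]
    if (is.null(m) || m$k_bot == m$k_top) NA_real_ else 10^m$log_ic50
  }, numeric(1), USE.NAMES = FALSE)

  # files ---------------------------------------------------------------------
  fnames <- sprintf("frame_%04d.png", seq_along(times) - 1L)
  if (write_images) {
    for (i in seq_along(times)) {
      areas <- well_areas_at(layout, models, vehicle_model, times[i])
      img <- render_frame(layout, calib, areas, cfg, frame_seed = frame_seeds[i])
      png::writePNG(img, file.path(dir, fnames[i]))
    }
  }
  manifest <- frame_manifest(fnames, times, image_dir = dir,
                             check_files = write_images)
  write_manifest(manifest, file.path(dir, "manifest.csv"))
  write_plate_layout(layout, file.path(dir, "layout.csv"))
  write_calibration(calib, file.path(dir, "calibration.toml"))
  readr::write_csv(gt, file.path(dir, "ground_truth_wells.csv"))
  readr::write_csv(compounds, file.path(dir, "ground_truth_compounds.csv"))
  meta <- list(
    seed = as.integer(seed), window_min = window_min, times = times,
    render = unclass(cfg), calibration = unclass(calib),
    models = purrr::map(models, unclass),
    vehicle_model = unclass(vehicle_model)
  )
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(structure(
    list(dir = dir, manifest = manifest, layout = layout, calib = calib,
         cfg = cfg, times = times, ground_truth = gt, compounds = compounds,
         window_min = window_min, seed = as.integer(seed)),
    class = "synthetic_screen"
  ))
}
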