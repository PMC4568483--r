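#' Build a per-well area time series
#'
#' Extracts one well's measurements, drops points carrying any of the
#' excluded QC flags (by default `no_object` and `low_contrast` — frames
#' where nothing trustworthy was segmented), and sorts by time. Duplicate
#' time points for a well are a data error.
#'
#' @param measurements Measurements tibble from [measure_plate()].
#' @param well Well name.
#' @param exclude_flags QC flags whose presence excludes a point.
#' @return A tibble with columns `well`, `time_min`, `area_mm2`, `qc_flags`,
#'   sorted by time.
#' @export
build_timeseries <- function(measurements, well,
                             exclude_flags = c("no_object", "low_contrast")) {
  rows <- measurements[measurements$well == well, ]
  if (nrow(rows) == 0) {
    stop_spheroscreen(sprintf("no measurements for well %s", well),
                      "spheroscreen_data_error")
  }
  if (anyDuplicated(rows$time_min)) {
    stop_spheroscreen(sprintf("duplicate time points for well %s", well),
                      "spheroscreen_data_error")
  }
  if (length(exclude_flags) > 0) {
    flagged <- vapply(strsplit(rows$qc_flags, ";", fixed = TRUE),
                      function(f) any(f %in% exclude_flags), logical(1))
    rows <- rows[!flagged, ]
  }
  rows <- rows[order(rows$time_min), ]
  tibble(well = rows$well, time_min = rows$time_min,
         area_mm2 = rows$area_mm2, qc_flags = rows$qc_flags)
}

# closed-form OLS slope and R^2 of area on time
ols_slope <- function(t, a) {
  tm <- mean(t)
  am <- mean(a)
  sxx <- sum((t - tm)^2)
  sxy <- sum((t - tm) * (a - am))
  slope <- sxy / sxx
  sst <- sum((a - am)^2)
  r2 <- if (sst <= 0) 0 else {
    sse <- sst - slope * sxy
    1 - sse / sst
  }
  list(slope = slope, r_squared = max(0, min(1, r2)))
}

#' Contraction rate of a single well
#'
#' The assay endpoint: the ordinary least-squares slope of projected area
#' versus time over the initial window (time `<=` `window_min`, boundary
#' inclusive), negated so that contraction is positive and toxicity pushes
#' the endpoint towards zero. The slope is the exact closed form
#' `sum((t - tbar) (A - Abar)) / sum((t - tbar)^2)`; no smoothing is applied
#' first. A constant series has rate 0 and R^2 reported as 0.
#'
#' @param ts Time series from [build_timeseries()] (columns `time_min`,
#'   `area_mm2`; a `well` column is carried through if present).
#' @param window_min Endpoint window in minutes (default 150).
#' @return One-row tibble: `well`, `window_min`, `n_points`, `slope`
#'   (mm^2/min), `rate` (`-slope`), `r_squared`.
#' @export
contraction_rate <- function(ts, window_min = 150) {
  if (!is_number(window_min) || window_min <= 0) {
    stop_spheroscreen("window_min must be > 0", "spheroscreen_validation_error")
  }
  keep <- ts$time_min <= window_min
  t <- ts$time_min[keep]
  a <- ts$area_mm2[keep]
  if (length(t) < 3) {
    stop_spheroscreen(
      sprintf("well %s: only %d point(s) within the %g min window (need >= 3)",
              if ("well" %in% names(ts)) ts$well[1] else "?", length(t), window_min),
      "spheroscreen_insufficient_data"
    )
  }
  fit <- ols_slope(t, a)
  tibble(
    well = if ("well" %in% names(ts)) ts$well[1] else NA_character_,
    window_min = window_min, n_points = length(t),
    slope = fit$slope, rate = -fit$slope, r_squared = fit$r_squared
  )
}

#' Contraction rates for every well of a plate
#'
#' Applies [build_timeseries()] + [contraction_rate()] to each measured
#' well. Wells with fewer than 3 usable points inside the window are dropped
#' with a warning. When a layout is supplied, its annotation columns
#' (`compound`, `concentration_uM`, `role`, `replicate`, `solvent`) are
#' joined onto the result.
#'
#' @inheritParams build_timeseries
#' @param layout Optional [plate_layout] for annotation.
#' @param window_min Endpoint window, minutes.
#' @return A tibble with one row per usable well.
#' @export
contraction_rates <- function(measurements, layout = NULL, window_min = 150,
                              exclude_flags = c("no_object", "low_contrast")) {
  wells <- sort(unique(measurements$well))
  if (!is.null(layout)) wells <- intersect(wells, layout$well[layout$role != "empty"])
  rows <- purrr::map(wells, function(w) {
    tryCatch(
      contraction_rate(build_timeseries(measurements, w, exclude_flags), window_min),
      spheroscreen_insufficient_data = function(e) {
        rlang::warn(sprintf("excluding well %s: %s", w, conditionMessage(e)))
        NULL
      }
    )
  })
  rates <- dplyr::bind_rows(rows)
  if (!is.null(layout) && nrow(rates) > 0) {
    rates <- dplyr::left_join(
      rates,
      dplyr::select(as_tibble(layout), "well", "compound", "concentration_uM",
                    "role", "replicate", "solvent"),
      by = "well"
    )
  }
  rates
}

#' Normalize contraction rates to vehicle controls
#'
#' Divides each well's rate by the mean rate of the vehicle wells of the
#' same solvent group (compounds dissolved in DMSO are referenced to DMSO
#' vehicle wells, PBS-dissolved compounds to PBS vehicle wells, and so on);
#' with no solvent annotation all wells share one vehicle group. By
#' construction the vehicle wells of each group average exactly 1.
#'
#' @param rates Rates tibble from [contraction_rates()].
#' @param layout A [plate_layout] (used for `role`/`solvent` if `rates`
#'   lacks them).
#' @return `rates` with a `normalized_rate` column added.
#' @export
normalize_rates <- function(rates, layout = NULL) {
  if (!all(c("role", "solvent") %in% names(rates))) {
    if (is.null(layout)) {
      stop_spheroscreen("rates lack role/solvent columns; supply the layout",
                        "spheroscreen_normalization_error")
    }
    rates <- dplyr::left_join(
      rates,
      dplyr::select(as_tibble(layout), "well", "compound", "concentration_uM",
                    "role", "replicate", "solvent"),
      by = "well"
    )
  }
  groups <- split(seq_len(nrow(rates)), rates$solvent)
  rates$normalized_rate <- NA_real_
  for (g in names(groups)) {
    idx <- groups[[g]]
    veh <- rates$rate[idx][rates$role[idx] == "vehicle"]
    if (length(veh) == 0) {
      stop_spheroscreen(
        sprintf("no vehicle wells with a computed rate in solvent group '%s'", g),
        "spheroscreen_normalization_error"
      )
    }
    m <- mean(veh)
    if (!is.finite(m) || m <= 0) {
      stop_spheroscreen(
        sprintf("mean vehicle rate in solvent group '%s' is %g (<= 0); assay failed", g, m),
        "spheroscreen_normalization_error"
      )
    }
    rates$normalized_rate[idx] <- rates$rate[idx] / m
  }
  rates
}

#' Write or read a rates table CSV
#'
#' @param rates Rates tibble (annotated, normalized or not).
#' @param path CSV path.
#' @export
write_rates <- function(rates, path) {
  readr::write_csv(rates, path, na = "")
  invisible(path)
}

#' @rdname write_rates
#' @export
read_rates <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    well = readr::col_character(),
    compound = readr::col_character(),
    role = readr::col_character(),
    solvent = readr::col_character(),
    .default = readr::col_double()
  ), na = "")
}
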