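#' Pixel and well-grid calibration
#'
#' Calibration ties the image coordinate system to physical units and to the
#' plate geometry: a length scale (`mm_per_px`), the pixel position of the
#' center of well A1 (`grid_origin`, as 0-based `(row_px, col_px)`), the
#' spacing between adjacent well centers (`grid_pitch`), and the radius of
#' the circular analysis region placed at every well center
#' (`well_radius_px`). Whole-plate snapshots from a fixed camera have a fixed
#' grid, so calibration is supplied explicitly rather than estimated from
#' image content.
#'
#' @param mm_per_px Physical size of one pixel, mm (> 0).
#' @param grid_origin Numeric length-2, pixel `(row, col)` of the A1 well
#'   center (0-based).
#' @param grid_pitch Numeric length-2, pixel spacing `(d_row, d_col)` between
#'   adjacent well centers (> 0).
#' @param well_radius_px Radius (pixels) of the per-well analysis disk (> 0).
#' @return An object of class `plate_calibration`.
#' @examples
#' default_calibration()
#' @export
plate_calibration <- function(mm_per_px, grid_origin, grid_pitch, well_radius_px) {
  if (!is_number(mm_per_px) || mm_per_px <= 0) {
    stop_spheroscreen("mm_per_px must be a positive number", "spheroscreen_validation_error")
  }
  grid_origin <- as.numeric(grid_origin)
  grid_pitch <- as.numeric(grid_pitch)
  if (length(grid_origin) != 2 || any(!is.finite(grid_origin)) || any(grid_origin < 0)) {
    stop_spheroscreen("grid_origin must be two non-negative numbers", "spheroscreen_validation_error")
  }
  if (length(grid_pitch) != 2 || any(!is.finite(grid_pitch)) || any(grid_pitch <= 0)) {
    stop_spheroscreen("grid_pitch must be two positive numbers", "spheroscreen_validation_error")
  }
  if (!is_number(well_radius_px) || well_radius_px <= 0) {
    stop_spheroscreen("well_radius_px must be a positive number", "spheroscreen_validation_error")
  }
  structure(
    list(mm_per_px = mm_per_px, grid_origin = grid_origin,
         grid_pitch = grid_pitch, well_radius_px = well_radius_px),
    class = "plate_calibration"
  )
}

#' @export
print.plate_calibration <- function(x, ...) {
  cat("<plate_calibration>\n")
  cat(sprintf("  mm_per_px:      %g\n", x$mm_per_px))
  cat(sprintf("  grid_origin:    (%g, %g) px\n", x$grid_origin[1], x$grid_origin[2]))
  cat(sprintf("  grid_pitch:     (%g, %g) px\n", x$grid_pitch[1], x$grid_pitch[2]))
  cat(sprintf("  well_radius_px: %g\n", x$well_radius_px))
  invisible(x)
}

#' Default calibration for synthetic 1200x800 plate images
#'
#' Places an 8 x 12 grid with a 96-pixel pitch inside a 1200 x 800 frame at
#' 0.05 mm/px (so one well pitch is 4.8 mm on the rendered plate) with a
#' 40-pixel analysis radius per well.
#'
#' @return A [plate_calibration].
#' @export
default_calibration <- function() {
  plate_calibration(
    mm_per_px = 0.05,
    grid_origin = c(64, 74),
    grid_pitch = c(96, 96),
    well_radius_px = 40
  )
}

#' Read or write calibration as a TOML-style key/value file
#'
#' The file holds one `key = value` pair per line
#' (`mm_per_px`, `grid_origin_row_px`, `grid_origin_col_px`,
#' `grid_pitch_row_px`, `grid_pitch_col_px`, `well_radius_px`);
#' `#` starts a comment.
#'
#' @param path File path.
#' @return A [plate_calibration] (read) or `path` invisibly (write).
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) {
    stop_spheroscreen(sprintf("calibration file not found: %s", path), "spheroscreen_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) {
    stop_spheroscreen(sprintf("malformed calibration line: %s", lines[bad][1]),
                      "spheroscreen_io_error")
  }
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[`, "", 2L))))
  need <- c("mm_per_px", "grid_origin_row_px", "grid_origin_col_px",
            "grid_pitch_row_px", "grid_pitch_col_px", "well_radius_px")
  if (!all(need %in% keys)) {
    stop_spheroscreen(
      sprintf("calibration file missing key(s): %s",
              paste(setdiff(need, keys), collapse = ", ")),
      "spheroscreen_io_error"
    )
  }
  v <- setNames(vals, keys)
  plate_calibration(
    mm_per_px = v[["mm_per_px"]],
    grid_origin = c(v[["grid_origin_row_px"]], v[["grid_origin_col_px"]]),
    grid_pitch = c(v[["grid_pitch_row_px"]], v[["grid_pitch_col_px"]]),
    well_radius_px = v[["well_radius_px"]]
  )
}

#' @rdname read_calibration
#' @param calib A [plate_calibration].
#' @export
write_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "plate_calibration"))
  writeLines(c(
    "# spheroscreen plate calibration",
    sprintf("mm_per_px = %.17g", calib$mm_per_px),
    sprintf("grid_origin_row_px = %.17g", calib$grid_origin[1]),
    sprintf("grid_origin_col_px = %.17g", calib$grid_origin[2]),
    sprintf("grid_pitch_row_px = %.17g", calib$grid_pitch[1]),
    sprintf("grid_pitch_col_px = %.17g", calib$grid_pitch[2]),
    sprintf("well_radius_px = %.17g", calib$well_radius_px)
  ), path)
  invisible(path)
}
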