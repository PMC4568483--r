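#' Read a plate image as a normalized grayscale frame
#'
#' Supports PNG, TIFF (8/16-bit) and JPEG. Color images are converted to
#' luminance with the Rec. 709 weights (0.2126 R + 0.7152 G + 0.0722 B);
#' alpha channels are ignored. Integer pixel values are rescaled to `[0, 1]`
#' by the dtype maximum (done by the format readers).
#'
#' @param path Image file path; format is chosen by extension.
#' @return A numeric matrix (rows x columns, origin top-left) in `[0, 1]`.
#' @export
read_frame <- function(path) {
  if (!file.exists(path)) {
    stop_spheroscreen(sprintf("image file not found: %s", path), "spheroscreen_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      tif = ,
      tiff = tiff::readTIFF(path),
      jpg = ,
      jpeg = jpeg::readJPEG(path),
      stop_spheroscreen(sprintf("unsupported image format '.%s': %s", ext, path),
                        "spheroscreen_io_error")
    ),
    error = function(e) {
      stop_spheroscreen(sprintf("failed to read image %s: %s", path, conditionMessage(e)),
                        "spheroscreen_io_error")
    }
  )
  px <- to_luminance(img)
  if (any(!is.finite(px))) {
    stop_spheroscreen(sprintf("non-finite pixel values in %s", path), "spheroscreen_io_error")
  }
  px
}

# collapse an H x W x C array to grayscale luminance; matrices pass through
to_luminance <- function(img) {
  if (is.matrix(img)) return(img)
  stopifnot(length(dim(img)) == 3)
  nc <- dim(img)[3]
  if (nc == 1) return(img[, , 1])
  if (nc == 2) return(img[, , 1]) # gray + alpha
  0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
}

#' Write a grayscale frame to disk
#'
#' PNG frames are written 8-bit, TIFF frames 16-bit; values are clipped to
#' `[0, 1]` first.
#'
#' @param pixels Numeric matrix in `[0, 1]`.
#' @param path Output path (`.png` or `.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
write_frame <- function(pixels, path) {
  stopifnot(is.matrix(pixels))
  pixels <- pmin(pmax(pixels, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(pixels, path),
    tif = ,
    tiff = tiff::writeTIFF(pixels, path, bits.per.sample = 16L),
    stop_spheroscreen(sprintf("unsupported output format '.%s'", ext), "spheroscreen_io_error")
  )
  invisible(path)
}

#' Read an acquisition manifest
#'
#' The manifest is a CSV with columns `filename,time_min` assigning an
#' acquisition time (minutes since compound addition / magnet removal) to
#' every frame of a time-lapse sequence. Filenames are resolved against
#' `image_dir`. Frames are returned sorted by time regardless of row or
#' filename order; duplicate filenames, duplicate or negative times, and
#' missing files are errors.
#'
#' @param path Manifest CSV path.
#' @param image_dir Directory holding the image files (defaults to the
#'   manifest's directory).
#' @param check_files If `TRUE` (default), verify every referenced file exists.
#' @return A tibble of class `frame_manifest` with columns `frame_id`
#'   (ordinal after time sorting), `file` (full path) and `time_min`.
#' @export
read_manifest <- function(path, image_dir = dirname(path), check_files = TRUE) {
  if (!file.exists(path)) {
    stop_spheroscreen(sprintf("manifest file not found: %s", path), "spheroscreen_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(
    filename = readr::col_character(),
    time_min = readr::col_double()
  ))
  frame_manifest(raw$filename, raw$time_min, image_dir = image_dir,
                 check_files = check_files)
}

#' @rdname read_manifest
#' @param filename Character vector of image file names.
#' @param time_min Numeric vector of acquisition times (minutes).
#' @export
frame_manifest <- function(filename, time_min, image_dir = ".", check_files = TRUE) {
  if (length(filename) != length(time_min) || length(filename) == 0) {
    stop_spheroscreen("manifest needs matching, non-empty filename and time_min",
                      "spheroscreen_manifest_error")
  }
  if (anyDuplicated(filename)) {
    dup <- unique(filename[duplicated(filename)])
    stop_spheroscreen(sprintf("duplicate manifest filename(s): %s", paste(dup, collapse = ", ")),
                      "spheroscreen_manifest_error")
  }
  if (any(!is.finite(time_min)) || any(time_min < 0)) {
    stop_spheroscreen("manifest times must be finite and non-negative",
                      "spheroscreen_manifest_error")
  }
  ord <- order(time_min)
  time_min <- time_min[ord]
  filename <- filename[ord]
  if (any(diff(time_min) <= 0)) {
    stop_spheroscreen("manifest times must be strictly increasing (duplicate timestamps?)",
                      "spheroscreen_manifest_error")
  }
  file <- file.path(image_dir, filename)
  if (check_files) {
    missing <- file[!file.exists(file)]
    if (length(missing) > 0) {
      stop_spheroscreen(sprintf("missing image file(s): %s", paste(missing, collapse = ", ")),
                        "spheroscreen_io_error")
    }
  }
  structure(
    tibble(frame_id = seq_along(file), file = file, time_min = time_min),
    class = c("frame_manifest", class(tibble()))
  )
}

#' @rdname read_manifest
#' @param manifest A `frame_manifest`.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_csv(
    tibble(filename = basename(manifest$file), time_min = manifest$time_min),
    path
  )
  invisible(path)
}
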