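#' Segmentation configuration
#'
#' Tunables for the per-well spheroid segmentation. The threshold is Otsu's
#' method computed on the pixels of the well's analysis disk, accepted only
#' when the separation between the local background (median of the outer
#' annulus) and the candidate foreground mean exceeds `contrast_floor`;
#' otherwise the well is flagged `low_contrast` and measured as empty. A
#' morphological opening removes speckle, holes are filled, and the largest
#' 8-connected component is taken as the spheroid.
#'
#' @param contrast_floor Minimum background-minus-foreground intensity
#'   separation to accept a segmentation (default 0.05).
#' @param opening_radius Radius (px) of the opening structuring element
#'   (default 1; 0 disables opening).
#' @param annulus_frac Fraction of the analysis radius forming the outer
#'   background annulus (default 0.2, i.e. the outer 20%).
#' @return An object of class `seg_config`.
#' @export
seg_config <- function(contrast_floor = 0.05, opening_radius = 1, annulus_frac = 0.2) {
  stopifnot(is_number(contrast_floor), contrast_floor >= 0,
            is_number(opening_radius), opening_radius >= 0,
            is_number(annulus_frac), annulus_frac > 0, annulus_frac < 1)
  structure(
    list(contrast_floor = contrast_floor,
         opening_radius = as.integer(opening_radius),
         annulus_frac = annulus_frac),
    class = "seg_config"
  )
}

#' Locate well analysis regions in a frame
#'
#' Purely geometric: each non-empty layout well gets a circular region of
#' interest centered at `grid_origin + (row * d_row, col * d_col)` with
#' radius `well_radius_px`. Any region extending beyond the frame is a
#' calibration error naming the offending well.
#'
#' @param layout A [plate_layout].
#' @param calib A [plate_calibration].
#' @param frame_dim Frame size `(rows, cols)` in pixels.
#' @return A tibble with columns `well`, `center_row`, `center_col`
#'   (0-based pixel coordinates) and `radius_px`.
#' @export
locate_wells <- function(layout, calib, frame_dim) {
  stopifnot(inherits(layout, "plate_layout"), inherits(calib, "plate_calibration"))
  frame_dim <- as.numeric(frame_dim)
  stopifnot(length(frame_dim) == 2)
  active <- layout[layout$role != "empty", ]
  rois <- tibble(
    well = active$well,
    center_row = calib$grid_origin[1] + active$row * calib$grid_pitch[1],
    center_col = calib$grid_origin[2] + active$col * calib$grid_pitch[2],
    radius_px = calib$well_radius_px
  )
  r <- rois$radius_px
  out <- rois$center_row - r < 0 | rois$center_row + r > frame_dim[1] - 1 |
    rois$center_col - r < 0 | rois$center_col + r > frame_dim[2] - 1
  if (any(out)) {
    stop_spheroscreen(
      sprintf("well region(s) outside the %gx%g frame: %s", frame_dim[1], frame_dim[2],
              paste(rois$well[out], collapse = ", ")),
      "spheroscreen_calibration_error"
    )
  }
  rois
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so merge any labels
# that touch diagonally (union-find over diagonal label pairs)
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n <= 1) return(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nrow(lab), -ncol(lab)]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-nrow(lab), -1]), as.vector(lab[-1, -ncol(lab)]))
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i] <<- parent[parent[i]]; i }
  for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(n), find, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- dense[lab[lab > 0]]
  out
}

# Otsu's threshold on a pixel vector: 256-bin histogram, pick the cut
# maximizing between-class variance; returns the upper edge of the chosen bin
otsu_threshold <- function(v, levels = 256L) {
  r <- range(v)
  span <- r[2] - r[1]
  if (span <= 0) return(r[1])
  b <- pmin(as.integer((v - r[1]) / span * levels), levels - 1L)
  h <- tabulate(b + 1L, nbins = levels)
  mids <- (seq_len(levels) - 0.5) / levels
  w1 <- cumsum(h)
  w2 <- w1[levels] - w1
  s1 <- cumsum(h * mids)
  m1 <- s1 / w1
  m2 <- (s1[levels] - s1) / w2
  bc <- w1 * w2 * (m1 - m2)^2
  bc[!is.finite(bc)] <- -1
  k <- which.max(bc[-levels])
  r[1] + span * k / levels
}

# precomputed per-ROI geometry so per-frame segmentation touches no tibbles
roi_geometry <- function(roi, cfg) {
  cr <- roi$center_row
  cc <- roi$center_col
  R <- roi$radius_px
  rows <- (floor(cr - R) + 1L):(ceiling(cr + R) + 1L)
  cols <- (floor(cc - R) + 1L):(ceiling(cc + R) + 1L)
  d2 <- outer(((rows - 1) - cr)^2, ((cols - 1) - cc)^2, `+`)
  in_roi <- d2 <= R^2
  list(
    well = roi$well, rows = rows, cols = cols,
    nr = length(rows), nc = length(cols),
    in_roi = in_roi,
    roi_idx = which(in_roi),
    ann_idx = which(in_roi & d2 >= ((1 - cfg$annulus_frac) * R)^2),
    ring = in_roi & d2 > (R - 1)^2
  )
}

# core per-well segmentation on a precomputed geometry; returns a plain list
segment_core <- function(pixels, g, cfg, brush = NULL) {
  sub <- pixels[g$rows, g$cols, drop = FALSE]
  vals <- sub[g$roi_idx]
  empty <- function(flags) {
    list(area_px2 = 0L, centroid_row = NA_real_, centroid_col = NA_real_,
         circularity = NA_real_, qc_flags = paste(sort(flags), collapse = ";"))
  }
  if (diff(range(vals)) < 1e-12) return(empty("no_object"))

  thr <- otsu_threshold(vals)
  cand <- g$in_roi & sub < thr
  if (!any(cand)) return(empty("no_object"))
  bg <- median(sub[g$ann_idx])
  if (bg - mean(sub[cand]) < cfg$contrast_floor) return(empty("low_contrast"))

  mask <- matrix(0L, g$nr, g$nc)
  mask[cand] <- 1L
  if (cfg$opening_radius > 0) {
    if (is.null(brush)) brush <- EBImage::makeBrush(2L * cfg$opening_radius + 1L, shape = "disc")
    mask <- EBImage::opening(mask, brush)
  }
  mask <- EBImage::fillHull(mask)
  lab <- label8(mask > 0)
  n_comp <- max(lab)
  if (n_comp == 0) return(empty("no_object"))

  sizes <- tabulate(lab[lab > 0], nbins = n_comp)
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    means <- vapply(best, function(k) mean(sub[lab == k]), numeric(1))
    best <- best[means == min(means)]
    if (length(best) > 1) {
      cent <- vapply(best, function(k) {
        idx <- which(lab == k, arr.ind = TRUE)
        c(mean(idx[, 1]), mean(idx[, 2]))
      }, numeric(2))
      best <- best[order(cent[1, ], cent[2, ])]
    }
  }
  comp <- lab == best[1]
  area <- sum(comp)

  idx <- which(comp, arr.ind = TRUE)
  bb <- comp[min(idx[, 1]):max(idx[, 1]), min(idx[, 2]):max(idx[, 2]), drop = FALSE]
  per <- component_perimeter(bb)
  flags <- character(0)
  if (n_comp > 1) flags <- c(flags, "multi_object")
  if (any(comp & g$ring)) flags <- c(flags, "touches_roi_boundary")

  list(
    area_px2 = as.integer(area),
    centroid_row = mean(idx[, 1]) - 1 + (g$rows[1] - 1),
    centroid_col = mean(idx[, 2]) - 1 + (g$cols[1] - 1),
    circularity = if (per > 0) min(1, 4 * pi * area / per^2) else NA_real_,
    qc_flags = paste(sort(flags), collapse = ";")
  )
}

# perimeter estimate: boundary pixels (>= 1 background 4-neighbour) weighted 1,
# staircase/corner pixels (>= 2 background 4-neighbours) weighted sqrt(2)
component_perimeter <- function(comp) {
  nr <- nrow(comp)
  nc <- ncol(comp)
  p <- matrix(FALSE, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- comp
  nbg <- (!p[1:nr, 2:(nc + 1)]) + (!p[3:(nr + 2), 2:(nc + 1)]) +
    (!p[2:(nr + 1), 1:nc]) + (!p[2:(nr + 1), 3:(nc + 2)])
  b <- comp & nbg >= 1
  sum(ifelse(nbg[b] >= 2, sqrt(2), 1))
}

#' Segment the spheroid inside one well region
#'
#' Within the circular analysis region: the local background level is the
#' median of the outer annulus; Otsu's threshold on the region's pixels
#' defines dark candidate pixels; the candidate mask is opened, hole-filled
#' and labelled (8-connectivity); the largest component is the spheroid.
#' Equal-area ties go to the component with the darker mean intensity, then
#' to the smaller centroid row, then column. Degenerate inputs never raise:
#' they yield area 0 with a `no_object` (or `low_contrast`) flag.
#'
#' QC flags: `no_object` (nothing segmented), `low_contrast` (threshold
#' rejected by the contrast floor), `multi_object` (more than one component),
#' `touches_roi_boundary` (spheroid pixels on the region's outer ring, so the
#' area may be truncated).
#'
#' @param pixels Frame pixel matrix in `[0, 1]`.
#' @param roi One-row ROI as returned by [locate_wells()] (or a list with
#'   `well`, `center_row`, `center_col`, `radius_px`).
#' @param cfg A [seg_config].
#' @param mm_per_px Length scale used to report `area_mm2` (NA to skip).
#' @return A one-row tibble: `well`, `area_px2`, `area_mm2`, `centroid_row`,
#'   `centroid_col`, `circularity`, `qc_flags` (`;`-separated, `""` if none).
#' @export
segment_well <- function(pixels, roi, cfg = seg_config(), mm_per_px = NA_real_) {
  res <- segment_core(pixels, roi_geometry(roi, cfg), cfg)
  tibble(
    well = roi$well, area_px2 = res$area_px2,
    area_mm2 = if (is.na(mm_per_px)) NA_real_ else res$area_px2 * mm_per_px^2,
    centroid_row = res$centroid_row, centroid_col = res$centroid_col,
    circularity = res$circularity, qc_flags = res$qc_flags
  )
}

#' Measure projected areas for every well across a frame sequence
#'
#' Applies [segment_well()] to every non-empty well of every frame. Frames
#' may be given as a `frame_manifest` (files are read one at a time) or as a
#' list with elements `pixels` and `time_min`. All frames must share one
#' size; the output is ordered by `(well, time_min)` and is deterministic.
#'
#' @param frames A `frame_manifest` (see [read_manifest()]) or a list of
#'   `list(pixels =, time_min =)` frames.
#' @param layout A [plate_layout].
#' @param calib A [plate_calibration].
#' @param cfg A [seg_config].
#' @return A tibble with one row per (well, frame): `well`, `time_min`,
#'   `frame_id`, `area_px2`, `area_mm2`, `centroid_row`, `centroid_col`,
#'   `circularity`, `qc_flags`.
#' @export
measure_plate <- function(frames, layout, calib, cfg = seg_config()) {
  stopifnot(inherits(layout, "plate_layout"), inherits(calib, "plate_calibration"))
  if (inherits(frames, "frame_manifest")) {
    getter <- function(i) list(pixels = read_frame(frames$file[i]),
                               time_min = frames$time_min[i])
    n <- nrow(frames)
  } else {
    stopifnot(is.list(frames), length(frames) > 0)
    ord <- order(vapply(frames, function(f) f$time_min, numeric(1)))
    frames <- frames[ord]
    getter <- function(i) frames[[i]]
    n <- length(frames)
  }
  geoms <- NULL
  dim0 <- NULL
  out <- vector("list", n)
  for (i in seq_len(n)) {
    fr <- getter(i)
    if (is.null(dim0)) {
      dim0 <- dim(fr$pixels)
      rois <- locate_wells(layout, calib, frame_dim = dim0)
      geoms <- lapply(seq_len(nrow(rois)), function(j) roi_geometry(rois[j, ], cfg))
      brush <- if (cfg$opening_radius > 0)
        EBImage::makeBrush(2L * cfg$opening_radius + 1L, shape = "disc") else NULL
    } else if (!identical(dim(fr$pixels), dim0)) {
      stop_spheroscreen(
        sprintf("frame %d size (%s) differs from first frame (%s)",
                i, paste(dim(fr$pixels), collapse = "x"), paste(dim0, collapse = "x")),
        "spheroscreen_input_error"
      )
    }
    res <- lapply(geoms, function(g) segment_core(fr$pixels, g, cfg, brush))
    out[[i]] <- tibble(
      well = vapply(geoms, `[[`, "", "well"),
      time_min = fr$time_min,
      frame_id = i,
      area_px2 = vapply(res, `[[`, integer(1), "area_px2"),
      centroid_row = vapply(res, `[[`, numeric(1), "centroid_row"),
      centroid_col = vapply(res, `[[`, numeric(1), "centroid_col"),
      circularity = vapply(res, `[[`, numeric(1), "circularity"),
      qc_flags = vapply(res, `[[`, "", "qc_flags")
    )
  }
  res <- dplyr::bind_rows(out)
  res$area_mm2 <- res$area_px2 * calib$mm_per_px^2
  dplyr::arrange(
    dplyr::select(res, "well", "time_min", "frame_id", "area_px2", "area_mm2",
                  "centroid_row", "centroid_col", "circularity", "qc_flags"),
    .data$well, .data$time_min
  )
}

#' Read or write a measurements table
#'
#' CSV with the fixed header `well,time_min,frame_id,area_px2,area_mm2,`
#' `centroid_row,centroid_col,circularity,qc_flags`; values round-trip
#' losslessly.
#'
#' @param measurements A measurements tibble from [measure_plate()].
#' @param path CSV path.
#' @export
write_measurements <- function(measurements, path) {
  cols <- c("well", "time_min", "frame_id", "area_px2", "area_mm2",
            "centroid_row", "centroid_col", "circularity", "qc_flags")
  stopifnot(all(cols %in% names(measurements)))
  readr::write_csv(measurements[, cols], path, na = "")
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) {
    stop_spheroscreen(sprintf("measurements file not found: %s", path), "spheroscreen_io_error")
  }
  readr::read_csv(path, col_types = readr::cols(
    well = readr::col_character(),
    time_min = readr::col_double(),
    frame_id = readr::col_integer(),
    area_px2 = readr::col_integer(),
    area_mm2 = readr::col_double(),
    centroid_row = readr::col_double(),
    centroid_col = readr::col_double(),
    circularity = readr::col_double(),
    qc_flags = readr::col_character()
  ), na = "") |>
    dplyr::mutate(qc_flags = ifelse(is.na(.data$qc_flags), "", .data$qc_flags))
}
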