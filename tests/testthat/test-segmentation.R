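# single-well frame helper: one disk (or several) on a flat background
one_well_frame <- function(disks, size = c(101, 101), bg = 0.85, fg = 0.25) {
  img <- matrix(bg, size[1], size[2])
  for (d in disks) {
    idx <- spheroscreen:::disk_index(size[1], size[2], d$cr, d$cc, d$r)
    img[idx] <- fg
  }
  img
}

one_roi <- function(size = c(101, 101), radius = 45) {
  tibble::tibble(well = "A1", center_row = (size[1] - 1) / 2,
                 center_col = (size[2] - 1) / 2, radius_px = radius)
}

test_that("well regions are placed geometrically and validated", {
  lay <- default_screen_layout()
  calib <- default_calibration()
  rois <- locate_wells(lay, calib, c(800, 1200))
  expect_equal(nrow(rois), 96)
  a1 <- rois[rois$well == "A1", ]
  expect_equal(c(a1$center_row, a1$center_col), calib$grid_origin)
  expect_equal(nrow(dplyr::distinct(rois, center_row, center_col)), 96)

  bad <- plate_calibration(0.05, c(700, 1100), c(96, 96), 40)
  err <- tryCatch(locate_wells(lay, bad, c(800, 1200)), error = identity)
  expect_s3_class(err, "spheroscreen_calibration_error")
  expect_match(conditionMessage(err), "H12")
})

test_that("a clean disk is measured to within 3% of the rasterization oracle", {
  for (r in c(8, 12, 20, 32, 40)) {
    img <- one_well_frame(list(list(cr = 50, cc = 50, r = r)))
    m <- segment_well(img, one_roi(), mm_per_px = 0.05)
    oracle <- rasterized_disk_count(50, 50, r, nr = 101, nc = 101)
    expect_lt(abs(m$area_px2 - oracle) / oracle, 0.03)
    expect_equal(m$area_mm2, m$area_px2 * 0.05^2)
    expect_equal(m$centroid_row, 50, tolerance = 0.5)
    expect_equal(m$qc_flags, "")
  }
})

test_that("degenerate well contents yield flags, never errors", {
  # perfectly uniform region: nothing to segment
  flat <- matrix(0.85, 101, 101)
  m <- segment_well(flat, one_roi())
  expect_equal(m$area_px2, 0L)
  expect_equal(m$qc_flags, "no_object")
  expect_true(is.na(m$circularity))

  # faint shading below the contrast floor
  faint <- flat
  faint[40:60, 40:60] <- 0.83
  m2 <- segment_well(faint, one_roi())
  expect_equal(m2$area_px2, 0L)
  expect_equal(m2$qc_flags, "low_contrast")
})

test_that("with two objects the larger wins and multi_object is flagged", {
  img <- one_well_frame(list(list(cr = 35, cc = 35, r = 15),
                             list(cr = 70, cc = 70, r = 6)))
  m <- segment_well(img, one_roi())
  oracle <- rasterized_disk_count(35, 35, 15, nr = 101, nc = 101)
  expect_lt(abs(m$area_px2 - oracle) / oracle, 0.01)
  expect_match(m$qc_flags, "multi_object")
  expect_equal(m$centroid_row, 35, tolerance = 0.5)
})

test_that("objects on the region boundary are flagged but measured", {
  roi <- one_roi(radius = 30)
  img <- one_well_frame(list(list(cr = 50, cc = 75, r = 10)))
  m <- segment_well(img, roi)
  expect_match(m$qc_flags, "touches_roi_boundary")
  expect_gt(m$area_px2, 0)
})

test_that("rasterized disks are round (circularity >= 0.9 for radius >= 10)", {
  for (r in c(10, 15, 25, 40)) {
    img <- one_well_frame(list(list(cr = 50, cc = 50, r = r)))
    m <- segment_well(img, one_roi())
    expect_gte(m$circularity, 0.9)
    expect_lte(m$circularity, 1)
  }
})

test_that("segmentation tolerates uniform brightening and is deterministic", {
  lay <- mini_layout()
  calib <- mini_calibration()
  cfg <- mini_render_config(noise_sd = 0.02, vignette_strength = 0.1, seed = 2L)
  areas <- setNames(rep(1.8, nrow(lay)), lay$well)
  img <- render_frame(lay, calib, areas, cfg, frame_seed = 5L)

  m1 <- measure_plate(list(list(pixels = img, time_min = 0)), lay, calib)
  m2 <- measure_plate(list(list(pixels = img, time_min = 0)), lay, calib)
  expect_identical(m1, m2)

  brighter <- pmin(img + 0.1, 1)
  m3 <- measure_plate(list(list(pixels = brighter, time_min = 0)), lay, calib)
  expect_lt(max(abs(m3$area_px2 - m1$area_px2) / m1$area_px2), 0.01)
})

test_that("measured areas are non-increasing on a noiseless shrinking sequence", {
  lay <- mini_layout()
  calib <- mini_calibration()
  cfg <- mini_render_config(noise_sd = 0, vignette_strength = 0, seed = 4L)
  model <- contraction_model()
  times <- seq(0, 600, by = 60)
  frames <- lapply(seq_along(times), function(i) {
    a <- area_trajectory(model, 0, times[i])
    list(pixels = render_frame(lay, calib, setNames(rep(a, nrow(lay)), lay$well),
                               cfg, frame_seed = i),
         time_min = times[i])
  })
  m <- measure_plate(frames, lay, calib)
  for (w in unique(m$well)) {
    series <- m$area_px2[m$well == w][order(m$time_min[m$well == w])]
    expect_true(all(diff(series) <= 0))
  }

  # frame order must not matter
  m_shuffled <- measure_plate(frames[c(4, 1, 11, 2, 3, 10, 5, 9, 6, 8, 7)],
                              lay, calib)
  expect_identical(m, m_shuffled)

  # mismatched frame sizes are an input error
  bad <- frames[1:2]
  bad[[2]]$pixels <- matrix(0.5, 60, 60)
  expect_error(measure_plate(bad, lay, calib), class = "spheroscreen_input_error")
})
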