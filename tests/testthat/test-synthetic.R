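test_that("area trajectories honor the kinetic model's boundary cases", {
  m <- contraction_model(A0 = 2, A_inf = 0.8, k_top = 0.003, k_bot = 0,
                         log_ic50 = 2, slope_s = 0.25)
  # t = 0 gives A0 for any concentration
  for (conc in c(0, 1, 100, 1e6)) {
    expect_equal(area_trajectory(m, conc, 0), 2)
  }
  # saturating dose with k_bot = 0: no contraction at all
  expect_equal(area_trajectory(m, 1e12, c(0, 100, 600)), rep(2, 3),
               tolerance = 1e-9)
  # at c = IC50 the rate constant is exactly the logistic midpoint
  expect_identical(rate_constant(m, 100), (m$k_top + m$k_bot) / 2)
  # strictly decreasing when k > 0
  a <- area_trajectory(m, 0, seq(0, 600, by = 4))
  expect_true(all(diff(a) < 0))
  expect_error(area_trajectory(m, 10, c(-1, 0)),
               class = "spheroscreen_validation_error")
})

test_that("rate constants decrease monotonically with dose", {
  m <- contraction_model(log_ic50 = log10(46.7))
  conc <- sort(10^runif(50, -2, 4))
  k <- rate_constant(m, conc)
  expect_true(all(diff(k) <= 0))
  # hence secant contraction rates are non-increasing in dose
  rate <- (area_trajectory(m, 0, 0) -
             vapply(conc, function(cc) area_trajectory(m, cc, 150), 1)) / 150
  expect_true(all(diff(rate) <= 1e-12))
})

test_that("rendered disks match the independent rasterization oracle", {
  lay <- mini_layout()
  calib <- mini_calibration()
  cfg <- mini_render_config(noise_sd = 0, vignette_strength = 0, seed = 7L)
  r_px <- 14
  area_mm2 <- pi * (r_px * calib$mm_per_px)^2
  areas <- setNames(rep(area_mm2, nrow(lay)), lay$well)
  img <- render_frame(lay, calib, areas, cfg, frame_seed = 1L)

  rois <- locate_wells(lay, calib, dim(img))
  jit <- spheroscreen:::well_jitter(sort(lay$well), calib, cfg$seed)
  for (i in seq_len(nrow(rois))) {
    cr <- rois$center_row[i] + jit$d_row[match(rois$well[i], jit$well)]
    cc <- rois$center_col[i] + jit$d_col[match(rois$well[i], jit$well)]
    oracle <- rasterized_disk_count(cr, cc, r_px, nr = 120, nc = 360)
    count <- sum(img[max(1, floor(cr - r_px)):ceiling(cr + r_px + 2),
                     max(1, floor(cc - r_px)):ceiling(cc + r_px + 2)] < 0.5)
    expect_equal(count, oracle)
  }
})

test_that("rendering is bit-identical under identical seeds", {
  lay <- mini_layout()
  calib <- mini_calibration()
  cfg <- mini_render_config(seed = 11L)
  areas <- setNames(rep(1.5, nrow(lay)), lay$well)
  f1 <- render_frame(lay, calib, areas, cfg, frame_seed = 99L)
  f2 <- render_frame(lay, calib, areas, cfg, frame_seed = 99L)
  expect_identical(f1, f2)
  f3 <- render_frame(lay, calib, areas, cfg, frame_seed = 100L)
  expect_false(identical(f1, f3))
})

test_that("empty wells get no disk and oversized spheroids are refused", {
  lay <- plate_layout(data.frame(
    well = c("A1", "A2", "B1"), compound = c("X", NA, NA),
    concentration_uM = c(10, 0, 0), role = c("treatment", "vehicle", "empty"),
    replicate = c(1, 1, 1)
  ), n_rows = 2, n_cols = 2)
  calib <- plate_calibration(0.05, c(30, 30), c(60, 60), 25)
  cfg <- render_config(image_size = c(120, 120), noise_sd = 0,
                       vignette_strength = 0, seed = 3L)
  areas <- c(A1 = 1.5, A2 = 1.5)
  img <- render_frame(lay, calib, areas, cfg, frame_seed = 1L)
  # B1 region (around 90, 30) stays at background
  expect_true(all(img[85:115, 10:50] == cfg$background_level))

  big <- c(A1 = pi * (26 * 0.05)^2, A2 = 1.5)
  err <- tryCatch(render_frame(lay, calib, big, cfg, frame_seed = 1L),
                  error = identity)
  expect_s3_class(err, "spheroscreen_generation_error")
  expect_match(conditionMessage(err), "A1")
})

test_that("generated experiments carry exact ground truth", {
  dir <- withr::local_tempdir()
  times <- seq(0, 600, by = 4)
  sim <- generate_experiment(file.path(dir, "sim"), layout = mini_layout(),
                             models = mini_models(),
                             calib = mini_calibration(),
                             cfg = mini_render_config(),
                             times = times, seed = 5L, write_images = FALSE)
  expect_equal(length(sim$times), 151)
  gt <- sim$ground_truth
  # identical replicate kinetics: vehicle normalized rates exactly 1
  expect_identical(gt$true_normalized_rate[gt$role == "vehicle"],
                   rep(1, sum(gt$role == "vehicle")))
  # dose monotonicity of the truth
  trt <- gt[gt$role == "treatment", ]
  trt <- trt[order(trt$concentration_uM), ]
  expect_true(all(diff(trt$true_rate) <= 1e-15))
  expect_equal(sim$compounds$true_ic50_uM, 100)

  # a layout without vehicle wells is refused
  no_veh <- plate_layout(data.frame(
    well = c("A1", "A2"), compound = "X", concentration_uM = c(1, 10),
    role = "treatment", replicate = c(1, 1)
  ), n_rows = 1, n_cols = 2)
  expect_error(
    generate_experiment(file.path(dir, "noveh"), layout = no_veh,
                        models = mini_models(), calib = mini_calibration(),
                        cfg = mini_render_config(), times = c(0, 4, 8),
                        write_images = FALSE),
    class = "spheroscreen_generation_error"
  )
})

test_that("saturating dose with k_bot = 0 has true normalized rate 0", {
  lay <- plate_layout(data.frame(
    well = c("A1", "A2", "A3"), compound = c("X", NA, NA),
    concentration_uM = c(1e9, 0, 0), role = c("treatment", "vehicle", "vehicle"),
    replicate = c(1, 1, 2)
  ), n_rows = 1, n_cols = 3)
  dir <- withr::local_tempdir()
  sim <- generate_experiment(file.path(dir, "sat"), layout = lay,
                             models = list(X = contraction_model(log_ic50 = 2)),
                             calib = mini_calibration(),
                             cfg = mini_render_config(),
                             times = c(0, 75, 150), write_images = FALSE)
  expect_equal(sim$ground_truth$true_normalized_rate[1], 0, tolerance = 1e-12)
})

test_that("the kinetics stage recovers generator truth from noiseless areas", {
  # feed exact model areas (no imaging) through the endpoint computation
  m <- contraction_model()
  times <- seq(0, 600, by = 4)
  for (conc in c(0, 30, 100, 300)) {
    a <- area_trajectory(m, conc, times)
    ts <- tibble::tibble(well = "W", time_min = times, area_mm2 = a,
                         qc_flags = "")
    rate <- contraction_rate(ts, window_min = 150)$rate
    # OLS equals the independent direct-summation oracle to 1e-12
    keep <- times <= 150
    expect_equal(rate, -ols_slope_oracle(times[keep], a[keep]), tolerance = 1e-12)
    # and tracks the true secant rate closely (mild convexity bias only)
    secant <- (a[1] - area_trajectory(m, conc, 150)) / 150
    if (secant > 0) expect_lt(abs(rate - secant) / secant, 0.1)
  }
})
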