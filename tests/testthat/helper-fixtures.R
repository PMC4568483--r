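# Shared fixtures, built in code at test time.

# independent rasterized-disk oracle: count pixels whose centers fall inside
# the circle, by direct enumeration (no shared code with the renderer)
rasterized_disk_count <- function(cr, cc, r, nr = ceiling(cr + r) + 2,
                                  nc = ceiling(cc + r) + 2) {
  n <- 0L
  for (i in 0:(nr - 1)) {
    for (j in 0:(nc - 1)) {
      if ((i - cr)^2 + (j - cc)^2 <= r^2) n <- n + 1L
    }
  }
  n
}

# direct-summation OLS oracle: explicit loops, no vectorized shortcuts
ols_slope_oracle <- function(t, a) {
  n <- length(t)
  tm <- 0; am <- 0
  for (i in seq_len(n)) { tm <- tm + t[i]; am <- am + a[i] }
  tm <- tm / n; am <- am / n
  sxy <- 0; sxx <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (t[i] - tm) * (a[i] - am)
    sxx <- sxx + (t[i] - tm)^2
  }
  sxy / sxx
}

# grid-search Boltzmann oracle: for each (x0, dx) the model is linear in
# (A1, A2), solved exactly; returns the best grid point
boltzmann_grid_oracle <- function(x, y, x0_grid, dx_grid) {
  best <- list(ss = Inf)
  for (x0 in x0_grid) {
    for (dx in dx_grid) {
      L <- 1 / (1 + exp((x - x0) / dx))
      fit <- stats::lm.fit(cbind(1, L), y)
      ss <- sum(fit$residuals^2)
      if (ss < best$ss) {
        best <- list(ss = ss, x0 = x0, dx = dx,
                     A2 = fit$coefficients[1],
                     A1 = fit$coefficients[1] + fit$coefficients[2])
      }
    }
  }
  best
}

# a minimal single-compound plate on a 2 x 6 grid: 4 doses x 2 reps + 3
# vehicle wells + 1 spare vehicle
mini_layout <- function() {
  plate_layout(data.frame(
    well = c("A1", "A2", "A3", "A4", "A5", "A6", "B1", "B2", "B3", "B4", "B5", "B6"),
    compound = c(rep("drugX", 8), rep(NA, 4)),
    concentration_uM = c(rep(c(10, 32, 100, 320), each = 2), rep(0, 4)),
    role = c(rep("treatment", 8), rep("vehicle", 4)),
    replicate = c(rep(1:2, 4), 1:4),
    solvent = "PBS"
  ), n_rows = 2, n_cols = 6)
}

mini_calibration <- function() {
  plate_calibration(mm_per_px = 0.05, grid_origin = c(30, 30),
                    grid_pitch = c(60, 60), well_radius_px = 25)
}

mini_render_config <- function(...) {
  render_config(image_size = c(120, 360), ...)
}

mini_models <- function() {
  list(drugX = contraction_model(log_ic50 = log10(100)))
}

# memoised full-size default screen (generated + measured once per run);
# shared by the acceptance tests
.screen_cache <- new.env(parent = emptyenv())
full_screen_fixture <- function() {
  if (!is.null(.screen_cache$screen)) return(.screen_cache$screen)
  dir <- file.path(tempdir(), "spheroscreen-full-screen")
  sim <- generate_experiment(dir, seed = 20260925L, overwrite = TRUE)
  man <- read_manifest(file.path(dir, "manifest.csv"))
  t0 <- Sys.time()
  measurements <- measure_plate(man, sim$layout, sim$calib)
  measure_secs <- as.numeric(Sys.time() - t0, units = "secs")
  .screen_cache$screen <- list(sim = sim, manifest = man,
                               measurements = measurements,
                               measure_secs = measure_secs)
  .screen_cache$screen
}

# screen-level rates fixture shared by report and pipeline tests
make_screen_rates <- function(seed = 5, noise = 0.02) {
  withr::with_seed(seed, {
    doses <- 10^seq(0.5, 2.5, length.out = 4)
    resp <- function(conc, ic50) 1 / (1 + exp((log10(conc) - log10(ic50)) / 0.25))
    act <- tibble::tibble(
      well = sprintf("A%d", 1:12),
      compound = "hit", concentration_uM = rep(doses, each = 3),
      role = "treatment", solvent = "PBS",
      normalized_rate = resp(rep(doses, each = 3), 50) + rnorm(12, 0, noise)
    )
    flat <- tibble::tibble(
      well = sprintf("B%d", 1:12),
      compound = "dud", concentration_uM = rep(doses, each = 3),
      role = "treatment", solvent = "PBS",
      normalized_rate = 1 + rnorm(12, 0, noise)
    )
    veh <- tibble::tibble(
      well = sprintf("C%d", 1:6), compound = NA_character_,
      concentration_uM = 0, role = "vehicle", solvent = "PBS",
      normalized_rate = 1 + rnorm(6, 0, noise)
    )
    dplyr::bind_rows(act, flat, veh)
  })
}


# localized rasterized-disk oracle (enumeration restricted to a window
# around the disk; centers may be fractional)
rasterized_disk_count_at <- function(cr, cc, r) {
  n <- 0L
  for (i in (floor(cr - r) - 1):(ceiling(cr + r) + 1)) {
    for (j in (floor(cc - r) - 1):(ceiling(cc + r) + 1)) {
      if ((i - cr)^2 + (j - cc)^2 <= r^2) n <- n + 1L
    }
  }
  n
}
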