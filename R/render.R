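#' Rendering configuration for synthetic plate images
#'
#' Controls how the synthetic generator turns per-well areas into an image:
#' a bright light-pad background carrying a radial vignette, dark filled
#' disks for the spheroids (their strong contrast comes from the magnetic
#' nanoparticles), an optional darker annulus at each well rim, and additive
#' Gaussian pixel noise.
#'
#' @param image_size Frame size `(rows_px, cols_px)`.
#' @param background_level Background intensity in `[0, 1]`.
#' @param spheroid_level Spheroid intensity in `[0, 1]`, below
#'   `background_level`.
#' @param vignette_strength Fractional intensity falloff at the image corner,
#'   in `[0, 1)`.
#' @param noise_sd Standard deviation of additive Gaussian noise, intensity
#'   units (>= 0).
#' @param well_rim Render a darker annulus just outside each analysis disk.
#' @param seed Integer seed controlling per-well center jitter (per-frame
#'   noise uses a separate frame seed).
#' @return An object of class `render_config`.
#' @export
render_config <- function(image_size = c(800, 1200), background_level = 0.85,
                          spheroid_level = 0.25, vignette_strength = 0.15,
                          noise_sd = 0.02, well_rim = FALSE, seed = 1L) {
  image_size <- as.integer(image_size)
  stopifnot(length(image_size) == 2, all(image_size > 0),
            is_number(background_level), is_number(spheroid_level),
            is_number(vignette_strength), is_number(noise_sd))
  if (spheroid_level >= background_level) {
    stop_spheroscreen("spheroid_level must be < background_level",
                      "spheroscreen_validation_error")
  }
  if (noise_sd < 0) {
    stop_spheroscreen("noise_sd must be >= 0", "spheroscreen_validation_error")
  }
  if (vignette_strength < 0 || vignette_strength >= 1) {
    stop_spheroscreen("vignette_strength must be in [0, 1)", "spheroscreen_validation_error")
  }
  structure(
    list(image_size = image_size, background_level = background_level,
         spheroid_level = spheroid_level, vignette_strength = vignette_strength,
         noise_sd = noise_sd, well_rim = isTRUE(well_rim), seed = as.integer(seed)),
    class = "render_config"
  )
}

# background field: background_level scaled by a radial quadratic vignette
render_background <- function(cfg) {
  nr <- cfg$image_size[1]
  nc <- cfg$image_size[2]
  if (cfg$vignette_strength == 0) {
    return(matrix(cfg$background_level, nr, nc))
  }
  rc <- (nr - 1) / 2
  cc <- (nc - 1) / 2
  d2r <- ((seq_len(nr) - 1) - rc)^2
  d2c <- ((seq_len(nc) - 1) - cc)^2
  d2 <- outer(d2r, d2c, `+`)
  dmax2 <- rc^2 + cc^2
  cfg$background_level * (1 - cfg$vignette_strength * d2 / dmax2)
}

# per-well center jitter (<= 5% of pitch per axis), fixed for an experiment:
# a printed spheroid is not perfectly centered but does not move between frames
well_jitter <- function(wells, calib, seed) {
  n <- length(wells)
  u <- withr::with_seed(as.integer(seed), stats::runif(2 * n, -0.05, 0.05))
  tibble(
    well = wells,
    d_row = u[seq_len(n)] * calib$grid_pitch[1],
    d_col = u[n + seq_len(n)] * calib$grid_pitch[2]
  )
}

#' Render one synthetic plate frame
#'
#' Draws, for every non-empty well, a filled disk of radius
#' `sqrt(area / pi) / mm_per_px` pixels at the (jittered) well center, at
#' `spheroid_level`, on the vignetted background; optionally a darker well
#' rim; then adds seeded Gaussian noise and clips to `[0, 1]`. Rendering is
#' deterministic given `cfg$seed` (jitter) and `frame_seed` (noise).
#'
#' @param layout A [plate_layout].
#' @param calib A [plate_calibration].
#' @param areas Named numeric vector of projected areas (mm^2), one entry per
#'   non-empty well in `layout`.
#' @param cfg A [render_config].
#' @param frame_seed Integer seed for this frame's noise.
#' @return A numeric pixel matrix in `[0, 1]`.
#' @export
render_frame <- function(layout, calib, areas, cfg = render_config(), frame_seed = 1L) {
  stopifnot(inherits(layout, "plate_layout"), inherits(calib, "plate_calibration"),
            inherits(cfg, "render_config"))
  wells <- layout$well[layout$role != "empty"]
  missing <- setdiff(wells, names(areas))
  if (length(missing) > 0) {
    stop_spheroscreen(sprintf("no area supplied for well(s): %s",
                              paste(missing, collapse = ", ")),
                      "spheroscreen_generation_error")
  }
  img <- render_background(cfg)
  nr <- nrow(img)
  nc <- ncol(img)

  centers <- locate_wells(layout, calib, frame_dim = c(nr, nc))
  jit <- well_jitter(sort(wells), calib, cfg$seed)
  centers <- dplyr::left_join(centers, jit, by = "well")
  centers$center_row <- centers$center_row + centers$d_row
  centers$center_col <- centers$center_col + centers$d_col

  if (cfg$well_rim) {
    r_in <- 1.05 * calib$well_radius_px
    r_out <- 1.15 * calib$well_radius_px
    idx <- unlist(lapply(seq_len(nrow(centers)), function(i) {
      annulus_index(nr, nc, centers$center_row[i], centers$center_col[i], r_in, r_out)
    }))
    img[idx] <- 0.6 * cfg$background_level
  }

  idx <- unlist(lapply(seq_len(nrow(centers)), function(i) {
    a <- areas[[centers$well[i]]]
    if (!is.finite(a) || a < 0) {
      stop_spheroscreen(sprintf("invalid area for well %s", centers$well[i]),
                        "spheroscreen_generation_error")
    }
    if (a == 0) return(integer(0))
    r_px <- sqrt(a / pi) / calib$mm_per_px
    if (r_px > calib$well_radius_px) {
      stop_spheroscreen(
        sprintf("spheroid in well %s (radius %.1f px) exceeds the analysis radius %g px",
                centers$well[i], r_px, calib$well_radius_px),
        "spheroscreen_generation_error"
      )
    }
    disk_index(nr, nc, centers$center_row[i], centers$center_col[i], r_px)
  }))
  img[idx] <- cfg$spheroid_level

  if (cfg$noise_sd > 0) {
    img <- img + withr::with_seed(as.integer(frame_seed),
                                  stats::rnorm(nr * nc, 0, cfg$noise_sd))
  }
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

# linear indices of pixels whose centers lie within r of (cr, cc); 0-based coords
disk_index <- function(nr, nc, cr, cc, r) {
  rows <- max(1L, floor(cr - r) + 1L):min(nr, ceiling(cr + r) + 1L)
  cols <- max(1L, floor(cc - r) + 1L):min(nc, ceiling(cc + r) + 1L)
  d2 <- outer(((rows - 1) - cr)^2, ((cols - 1) - cc)^2, `+`)
  hit <- which(d2 <= r^2, arr.ind = TRUE)
  rows[hit[, 1]] + (cols[hit[, 2]] - 1L) * nr
}

annulus_index <- function(nr, nc, cr, cc, r_in, r_out) {
  rows <- max(1L, floor(cr - r_out) + 1L):min(nr, ceiling(cr + r_out) + 1L)
  cols <- max(1L, floor(cc - r_out) + 1L):min(nc, ceiling(cc + r_out) + 1L)
  d2 <- outer(((rows - 1) - cr)^2, ((cols - 1) - cc)^2, `+`)
  hit <- which(d2 >= r_in^2 & d2 <= r_out^2, arr.ind = TRUE)
  rows[hit[, 1]] + (cols[hit[, 2]] - 1L) * nr
}
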