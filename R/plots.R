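#' Plot per-well contraction kinetics
#'
#' Projected area versus time for every well, coloured by concentration and
#' faceted by compound — the plate-level view of contraction kinetics.
#'
#' @param measurements Measurements tibble from [measure_plate()].
#' @param layout A [plate_layout] used to annotate wells.
#' @return A ggplot object.
#' @export
plot_kinetics <- function(measurements, layout) {
  d <- dplyr::left_join(
    measurements,
    dplyr::select(as_tibble(layout), "well", "compound", "concentration_uM", "role"),
    by = "well"
  )
  d <- d[d$role != "empty", ]
  d$compound <- ifelse(is.na(d$compound), "vehicle", d$compound)
  ggplot2::ggplot(d, ggplot2::aes(.data$time_min, .data$area_mm2,
                                  group = .data$well,
                                  colour = .data$concentration_uM)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::scale_colour_viridis_c(trans = "log1p", name = "conc (uM)") +
    ggplot2::facet_wrap(~compound) +
    ggplot2::labs(x = "time since compound addition (min)",
                  y = expression("projected area (mm"^2 * ")")) +
    ggplot2::theme_bw()
}

#' @rdname fit_boltzmann
#' @param object A `boltzmann_fit`.
#' @method autoplot boltzmann_fit
#' @export
autoplot.boltzmann_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble(x = seq(min(d$x), max(d$x), length.out = 200))
  grid$y <- predict(object, grid)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "log10 concentration (uM)", y = "response") +
    ggplot2::theme_bw()
  if (object$converged) {
    p <- p +
      ggplot2::geom_line(data = grid, colour = "firebrick") +
      ggplot2::geom_vline(xintercept = object$coef[["x0"]], linetype = "dashed")
  }
  p
}

#' Plot a screen's dose-response panels
#'
#' Normalized contraction rate against concentration for every compound,
#' with the fitted Boltzmann curve overlaid where one converged.
#'
#' @param report Report tibble from [screen_report()].
#' @param rates Normalized rates tibble from [normalize_rates()].
#' @return A ggplot object.
#' @export
plot_screen <- function(report, rates) {
  pts <- rates[rates$role %in% c("treatment", "positive_control") &
                 !is.na(rates$compound), ]
  anchor <- min(pts$concentration_uM[pts$concentration_uM > 0]) / 10
  pts$conc_plot <- pmax(pts$concentration_uM, anchor)
  curves <- purrr::map_dfr(seq_len(nrow(report)), function(i) {
    fit <- report$fit[[i]]
    if (is.null(fit)) return(NULL)
    g <- tibble(x = seq(min(fit$data$x), max(fit$data$x), length.out = 120))
    tibble(compound = report$compound[i], conc_plot = 10^g$x,
           normalized_rate = predict(fit, g))
  })
  p <- ggplot2::ggplot(pts, ggplot2::aes(.data$conc_plot, .data$normalized_rate)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~compound, scales = "free_x") +
    ggplot2::labs(x = "concentration (uM, log scale)",
                  y = "contraction rate (normalized to vehicle)") +
    ggplot2::theme_bw()
  if (nrow(curves) > 0) {
    p <- p + ggplot2::geom_line(data = curves, colour = "firebrick")
  }
  p
}
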