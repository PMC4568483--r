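#' Dose-dependent spheroid contraction kinetics
#'
#' Ground-truth model behind the synthetic plate generator. A freshly printed
#' spheroid's projected area decays mono-exponentially from its initial value
#' `A0` towards an equilibrium `A_inf` as viable cells rearrange and compact:
#'
#' \deqn{A(t) = A_{inf} + (A_0 - A_{inf}) e^{-k(c)\,t}}
#'
#' Toxicity slows compaction, so the rate constant falls with dose along a
#' logistic in log10 concentration:
#'
#' \deqn{k(c) = k_{bot} + \frac{k_{top} - k_{bot}}{1 + \exp\left(
#'   (\log_{10} c - \log_{10} IC_{50}) / s\right)}}
#'
#' with `k(0)` defined as the zero-dose limit `k_top`. At `c = IC50` the rate
#' is exactly `(k_top + k_bot) / 2`. This is a deliberately simple synthetic
#' model — real contraction curves need not be mono-exponential — but it
#' reproduces the qualitative kinetics (immediate contraction, slower at
#' higher dose) with an analytic ground truth for every downstream stage.
#'
#' The defaults describe the regime the package's synthetic experiments use:
#' `A0 = 2` mm^2 (initial spheroid diameter about a third of the well pitch),
#' `A_inf = 0.8` mm^2, and `k_top = 0.003`/min, under which an untreated
#' spheroid completes ~83% of its contraction over a 10 h acquisition and
#' loses ~18% of its initial area within the 150 min endpoint window.
#'
#' @param A0 Initial projected area, mm^2.
#' @param A_inf Asymptotic projected area, mm^2 (< `A0`).
#' @param k_top Contraction rate constant at zero dose, 1/min.
#' @param k_bot Rate constant at saturating dose, 1/min (`0 <= k_bot <= k_top`).
#'   Equal to `k_top` for a compound with no dose effect.
#' @param log_ic50 log10 of the half-maximal concentration, log10(uM).
#' @param slope_s Transition width in log10-concentration units (> 0).
#' @return An object of class `contraction_model`.
#' @examples
#' m <- contraction_model(log_ic50 = log10(82.8))
#' area_trajectory(m, conc = 82.8, times = c(0, 75, 150))
#' @export
contraction_model <- function(A0 = 2, A_inf = 0.8, k_top = 0.003, k_bot = 0,
                              log_ic50 = 2, slope_s = 0.25) {
  stopifnot(is_number(A0), is_number(A_inf), is_number(k_top), is_number(k_bot),
            is_number(log_ic50), is_number(slope_s))
  if (A_inf >= A0) {
    stop_spheroscreen("A_inf must be < A0", "spheroscreen_validation_error")
  }
  if (k_bot < 0 || k_bot > k_top) {
    stop_spheroscreen("need 0 <= k_bot <= k_top", "spheroscreen_validation_error")
  }
  if (slope_s <= 0) {
    stop_spheroscreen("slope_s must be > 0", "spheroscreen_validation_error")
  }
  structure(
    list(A0 = A0, A_inf = A_inf, k_top = k_top, k_bot = k_bot,
         log_ic50 = log_ic50, slope_s = slope_s),
    class = "contraction_model"
  )
}

#' @export
print.contraction_model <- function(x, ...) {
  cat(sprintf(
    "<contraction_model> A0=%g A_inf=%g mm^2; k: %g -> %g /min; IC50=%g uM (slope %g)\n",
    x$A0, x$A_inf, x$k_top, x$k_bot, 10^x$log_ic50, x$slope_s
  ))
  invisible(x)
}

#' Dose-dependent rate constant of a contraction model
#'
#' @param model A [contraction_model].
#' @param conc Concentrations, uM (vectorized; 0 gives the zero-dose limit
#'   `k_top`).
#' @return Rate constants, 1/min.
#' @export
rate_constant <- function(model, conc) {
  stopifnot(inherits(model, "contraction_model"))
  conc <- as.numeric(conc)
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop_spheroscreen("concentrations must be finite and >= 0", "spheroscreen_validation_error")
  }
  k <- rep(model$k_top, length(conc))
  pos <- conc > 0
  if (any(pos)) {
    z <- (log10(conc[pos]) - model$log_ic50) / model$slope_s
    k[pos] <- model$k_bot + (model$k_top - model$k_bot) / (1 + exp(z))
  }
  k
}

#' Projected-area trajectory under a contraction model
#'
#' @param model A [contraction_model].
#' @param conc A single concentration, uM.
#' @param times Acquisition times, minutes (non-negative).
#' @return Areas in mm^2, one per time point.
#' @export
area_trajectory <- function(model, conc, times) {
  stopifnot(inherits(model, "contraction_model"), is_number(conc))
  times <- as.numeric(times)
  if (any(!is.finite(times)) || any(times < 0)) {
    stop_spheroscreen("times must be finite and non-negative", "spheroscreen_validation_error")
  }
  k <- rate_constant(model, conc)
  model$A_inf + (model$A0 - model$A_inf) * exp(-k * times)
}
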