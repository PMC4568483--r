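#' Fit a Boltzmann sigmoidal dose-response curve
#'
#' Fits `f(x) = A2 + (A1 - A2) / (1 + exp((x - x0) / dx))` to responses
#' against `x = log10(concentration)` by nonlinear least squares — the
#' standard Boltzmann parameterization in which `A1` is the low-dose
#' asymptote, `A2` the high-dose asymptote, `x0` the transition midpoint
#' (so `IC50 = 10^x0`) and `dx > 0` the transition width in decades. This
#' form is shape-equivalent to the four-parameter logistic on log dose.
#'
#' Vehicle points (concentration 0) cannot sit on a log axis; they are
#' anchored one decade below the lowest tested dose (they represent the
#' uninhibited response and stabilize `A1`). Set `anchor_vehicle = FALSE` to
#' drop them instead.
#'
#' Optimization is deterministic multi-start Levenberg-Marquardt: `x0`
#' starts on a 5-point grid spanning the observed `x` range, `A1`/`A2` start
#' at the mean response at the extreme doses, `dx` at a quarter of the `x`
#' span (with `dx` bounded below at 1e-6); the converged start with the
#' lowest residual sum of squares wins. At least 4 distinct positive
#' concentrations and non-constant responses are required.
#'
#' @param data A data frame of dose-response observations.
#' @param conc,response Columns of `data` (tidy-eval) holding concentration
#'   in uM and the response (e.g. `normalized_rate`).
#' @param anchor_vehicle How to treat concentration-0 points (see above).
#' @param n_starts Number of `x0` grid starts (default 5).
#' @return An object of class `boltzmann_fit`: coefficients, `ic50_uM`,
#'   `residual_ss`, `converged`, `n_points`, standard errors, and the fitting
#'   data. Supports [coef()], [predict()], [tidy()], [glance()],
#'   [autoplot()].
#' @examples
#' d <- data.frame(conc = rep(10^(0:6 / 2), each = 3))
#' d$y <- 1 / (1 + exp((log10(d$conc) - log10(82.8)) / 0.3))
#' fit <- fit_boltzmann(d, conc, y)
#' ic50(fit)
#' @export
fit_boltzmann <- function(data, conc, response, anchor_vehicle = TRUE, n_starts = 5) {
  conc_v <- dplyr::pull(data, {{ conc }})
  y_v <- dplyr::pull(data, {{ response }})
  if (any(!is.finite(y_v)) || any(!is.finite(conc_v)) || any(conc_v < 0)) {
    stop_spheroscreen("concentrations must be >= 0 and responses finite",
                      "spheroscreen_fit_error")
  }
  pos <- conc_v > 0
  if (length(unique(conc_v[pos])) < 4) {
    stop_spheroscreen("need >= 4 distinct positive concentrations",
                      "spheroscreen_fit_error")
  }
  x <- rep(NA_real_, length(conc_v))
  x[pos] <- log10(conc_v[pos])
  anchor_x <- min(x[pos]) - 1
  if (any(!pos)) {
    if (anchor_vehicle) {
      x[!pos] <- anchor_x
    } else {
      x <- x[pos]
      y_v <- y_v[pos]
      conc_v <- conc_v[pos]
    }
  }
  if (var(y_v) == 0) {
    stop_spheroscreen("responses have zero variance (flat data)", "spheroscreen_fit_error")
  }

  df <- tibble(x = x, y = y_v, conc_uM = conc_v)
  span <- diff(range(df$x))
  lo <- df$y[df$x == min(df$x)]
  hi <- df$y[df$x == max(df$x)]
  a1_0 <- mean(lo)
  a2_0 <- mean(hi)
  dx_0 <- max(span / 4, 1e-3)
  x0_grid <- seq(min(df$x), max(df$x), length.out = n_starts)

  best <- NULL
  best_ss <- Inf
  for (x0_0 in x0_grid) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        y ~ A2 + (A1 - A2) / (1 + exp((x - x0) / dx)),
        data = df,
        start = list(A1 = a1_0, A2 = a2_0, x0 = x0_0, dx = dx_0),
        lower = c(A1 = -Inf, A2 = -Inf, x0 = -Inf, dx = 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                             ptol = 1e-12)
      )),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    ss <- sum(stats::resid(fit)^2)
    if (ss < best_ss) {
      best <- fit
      best_ss <- ss
    }
  }

  if (is.null(best)) {
    return(structure(
      list(coef = c(A1 = NA_real_, A2 = NA_real_, x0 = NA_real_, dx = NA_real_),
           se = NULL, ic50_uM = NA_real_, residual_ss = NA_real_,
           converged = FALSE, n_points = nrow(df),
           n_conc = length(unique(conc_v[conc_v > 0])),
           anchor_x = anchor_x, data = df),
      class = "boltzmann_fit"
    ))
  }
  cf <- coef(best)
  se <- tryCatch(summary(best)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 4), names(cf)))
  structure(
    list(coef = cf, se = se, ic50_uM = 10^cf[["x0"]], residual_ss = best_ss,
         converged = TRUE, n_points = nrow(df),
         n_conc = length(unique(conc_v[conc_v > 0])),
         anchor_x = anchor_x, data = df),
    class = "boltzmann_fit"
  )
}

#' Half-maximal inhibitory concentration from a Boltzmann fit
#'
#' By default the IC50 is the transition midpoint `10^x0`, where the
#' response is exactly halfway between the fitted asymptotes `A1` and `A2` —
#' the standard reading of the Boltzmann parameterization. Alternatively,
#' `mode = "half_response"` returns the concentration at which the fitted
#' curve crosses `A1 / 2` (absolute half of the low-dose response), when
#' that crossing exists.
#'
#' @param fit A `boltzmann_fit`.
#' @param mode `"midpoint"` (default) or `"half_response"`.
#' @return IC50 in uM.
#' @export
ic50 <- function(fit, mode = c("midpoint", "half_response")) {
  stopifnot(inherits(fit, "boltzmann_fit"))
  mode <- match.arg(mode)
  if (!fit$converged) {
    stop_spheroscreen("fit did not converge; IC50 unavailable",
                      "spheroscreen_not_converged")
  }
  cf <- fit$coef
  if (mode == "midpoint") return(unname(10^cf[["x0"]]))
  target <- cf[["A1"]] / 2
  denom <- target - cf[["A2"]]
  if (denom <= 0 || cf[["A1"]] - cf[["A2"]] <= denom) {
    stop_spheroscreen("fitted curve never crosses A1/2", "spheroscreen_fit_error")
  }
  z <- (cf[["A1"]] - cf[["A2"]]) / denom - 1
  unname(10^(cf[["x0"]] + cf[["dx"]] * log(z)))
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat("<boltzmann_fit>")
  if (!x$converged) {
    cat(" (not converged)\n")
    return(invisible(x))
  }
  cf <- x$coef
  cat(sprintf("\n  A1 = %.4g, A2 = %.4g, x0 = %.4g (IC50 = %.4g uM), dx = %.4g\n",
              cf[["A1"]], cf[["A2"]], cf[["x0"]], x$ic50_uM, cf[["dx"]]))
  cat(sprintf("  n = %d points, %d positive concentrations, RSS = %.4g\n",
              x$n_points, x$n_conc, x$residual_ss))
  invisible(x)
}

#' @export
coef.boltzmann_fit <- function(object, ...) object$coef

#' @export
predict.boltzmann_fit <- function(object, newdata = NULL, ...) {
  cf <- object$coef
  if (is.null(newdata)) {
    x <- object$data$x
  } else if (!is.null(newdata$x)) {
    x <- newdata$x
  } else if (!is.null(newdata$conc_uM)) {
    x <- ifelse(newdata$conc_uM > 0, log10(newdata$conc_uM), object$anchor_x)
  } else {
    stop_spheroscreen("newdata needs an 'x' or 'conc_uM' column", "spheroscreen_validation_error")
  }
  cf[["A2"]] + (cf[["A1"]] - cf[["A2"]]) / (1 + exp((x - cf[["x0"]]) / cf[["dx"]]))
}

#' @rdname fit_boltzmann
#' @param x A `boltzmann_fit`.
#' @param ... Unused.
#' @method tidy boltzmann_fit
#' @export
tidy.boltzmann_fit <- function(x, ...) {
  tibble(
    term = names(x$coef),
    estimate = unname(x$coef),
    std.error = if (is.null(x$se)) NA_real_ else unname(x$se[names(x$coef)])
  )
}

#' @rdname fit_boltzmann
#' @method glance boltzmann_fit
#' @export
glance.boltzmann_fit <- function(x, ...) {
  tibble(ic50_uM = x$ic50_uM, residual_ss = x$residual_ss,
         converged = x$converged, n_points = x$n_points, n_conc = x$n_conc)
}

#' Z'-factor screening-window statistic
#'
#' `Z' = 1 - 3 (sd_p + sd_n) / |mean_p - mean_n|` with sample standard
#' deviations (n - 1 denominator). Values in `[0.5, 1)` indicate a large
#' separation between the control distributions, i.e. an excellent assay;
#' `Z' <= 1` always. Equal group means make the statistic undefined and
#' raise a dedicated condition.
#'
#' @param pos,neg Numeric responses of the two control groups (>= 2 values
#'   each).
#' @return The Z'-factor (scalar).
#' @examples
#' z_prime(c(0.9, 1.0, 1.1), c(-0.1, 0, 0.1)) # 0.4
#' @export
z_prime <- function(pos, neg) {
  if (length(pos) < 2 || length(neg) < 2) {
    stop_spheroscreen("need >= 2 values per control group", "spheroscreen_validation_error")
  }
  sep <- abs(mean(pos) - mean(neg))
  if (sep == 0) {
    stop_spheroscreen("control means are equal; Z' undefined",
                      "spheroscreen_undefined_separation")
  }
  1 - 3 * (sd(pos) + sd(neg)) / sep
}

# tidy-eval front end shared by the ANOVA/Tukey functions
group_values <- function(data, response, group) {
  y <- dplyr::pull(data, {{ response }})
  g <- as.character(dplyr::pull(data, {{ group }}))
  if (any(!is.finite(y))) {
    stop_spheroscreen("responses must be finite", "spheroscreen_validation_error")
  }
  split(y, g)
}

anova_decomposition <- function(groups) {
  if (length(groups) < 2) {
    stop_spheroscreen("need >= 2 groups", "spheroscreen_validation_error")
  }
  n <- lengths(groups)
  if (any(n < 2)) {
    stop_spheroscreen("every group needs >= 2 values", "spheroscreen_validation_error")
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), n))
  fit <- stats::aov(y ~ g)
  tab <- summary(fit)[[1]]
  list(fit = fit, ss_between = tab[1, "Sum Sq"], ss_within = tab[2, "Sum Sq"],
       df_between = tab[1, "Df"], df_within = tab[2, "Df"],
       ms_within = tab[2, "Mean Sq"], groups = groups)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA (between/within sum-of-squares
#' decomposition via [stats::aov()]); the p-value comes from the F
#' distribution with `k - 1` and `N - k` degrees of freedom. Degenerate
#' cases are resolved explicitly: identical group means give `F = 0, p = 1`;
#' zero within-group variance with distinct means gives `F = Inf, p = 0`.
#'
#' @param data Data frame with one row per observation.
#' @param response,group Columns of `data` (tidy-eval): numeric response and
#'   grouping variable. Every group needs at least 2 observations.
#' @return One-row tibble: `statistic` (F), `p_value`, `df_between`,
#'   `df_within`.
#' @export
one_way_anova <- function(data, response, group) {
  dec <- anova_decomposition(group_values(data, {{ response }}, {{ group }}))
  f <- if (dec$ss_between <= 0) {
    0
  } else if (dec$ss_within <= 0) {
    Inf
  } else {
    (dec$ss_between / dec$df_between) / (dec$ss_within / dec$df_within)
  }
  p <- if (f == 0) 1 else if (is.infinite(f)) 0 else
    pf(f, dec$df_between, dec$df_within, lower.tail = FALSE)
  tibble(statistic = f, p_value = p,
         df_between = dec$df_between, df_within = dec$df_within)
}

#' Tukey honestly-significant-difference post hoc test
#'
#' All pairwise group comparisons after a one-way ANOVA. For each pair the
#' studentized-range statistic is
#' `q = |mean_i - mean_j| / sqrt(MSW / 2 * (1/n_i + 1/n_j))`
#' (the Tukey-Kramer form for unbalanced groups) and the family-wise p-value
#' comes from the studentized range distribution with `k` groups and `N - k`
#' error degrees of freedom ([stats::ptukey()]).
#'
#' @inheritParams one_way_anova
#' @param alpha Family-wise significance level (default 0.05).
#' @return A tibble sorted by `(group_i, group_j)` with columns `group_i`,
#'   `group_j`, `mean_diff` (mean_i - mean_j), `q_stat`, `p_value`,
#'   `significant`.
#' @export
tukey_hsd <- function(data, response, group, alpha = 0.05) {
  if (!is_number(alpha) || alpha <= 0 || alpha >= 1) {
    stop_spheroscreen("alpha must be in (0, 1)", "spheroscreen_validation_error")
  }
  dec <- anova_decomposition(group_values(data, {{ response }}, {{ group }}))
  gs <- dec$groups[order(names(dec$groups))]
  k <- length(gs)
  means <- vapply(gs, mean, numeric(1))
  ns <- lengths(gs)
  pairs <- utils::combn(names(gs), 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    gi <- pairs[1, j]
    gj <- pairs[2, j]
    se <- sqrt(dec$ms_within / 2 * (1 / ns[[gi]] + 1 / ns[[gj]]))
    diff <- means[[gi]] - means[[gj]]
    q <- if (se > 0) abs(diff) / se else if (diff == 0) 0 else Inf
    p <- if (is.infinite(q)) 0 else
      ptukey(q, nmeans = k, df = dec$df_within, lower.tail = FALSE)
    tibble(group_i = gi, group_j = gj, mean_diff = diff,
           q_stat = q, p_value = p, significant = p < alpha)
  })
  dplyr::arrange(out, .data$group_i, .data$group_j)
}
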