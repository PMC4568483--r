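#' Per-compound screening report
#'
#' For every compound in the layout: one-way ANOVA of normalized contraction
#' rates across its concentration groups (solvent-matched vehicle wells
#' included as the zero-dose group), Tukey HSD comparisons against vehicle,
#' and a Boltzmann dose-response fit. An IC50 is reported only when the
#' ANOVA shows a significant concentration effect (`p < alpha`) *and* the
#' fit converged; otherwise the compound is labelled `"n.s."` — a flat
#' negative control comes out `n.s.` by construction. A compound with a
#' single tested concentration is reported as unevaluable.
#'
#' @param rates Normalized rates tibble from [normalize_rates()] (needs
#'   `compound`, `concentration_uM`, `role`, `solvent`, `normalized_rate`).
#' @param alpha Significance level for the ANOVA gate (default 0.05).
#' @return A tibble with one row per compound: `compound`, `solvent`,
#'   `n_wells`, `n_conc`, `status` (`"ok"`, `"n.s."` or `"unevaluable"`),
#'   `anova_F`, `anova_p`, `significant`, `fit_converged`, `ic50_uM`,
#'   `ic50_label`, Boltzmann coefficients `A1`, `A2`, `x0`, `dx`,
#'   `residual_ss`, and list-columns `fit` (the `boltzmann_fit` or `NULL`)
#'   and `tukey` (comparisons vs vehicle).
#' @export
screen_report <- function(rates, alpha = 0.05) {
  need <- c("compound", "concentration_uM", "role", "solvent", "normalized_rate")
  if (!all(need %in% names(rates))) {
    stop_spheroscreen(
      sprintf("rates table missing column(s): %s",
              paste(setdiff(need, names(rates)), collapse = ", ")),
      "spheroscreen_validation_error"
    )
  }
  cmp_rows <- rates[rates$role %in% c("treatment", "positive_control", "negative_control") &
                      !is.na(rates$compound), ]
  compounds <- sort(unique(cmp_rows$compound))
  purrr::map_dfr(compounds, function(cmp) {
    sub <- cmp_rows[cmp_rows$compound == cmp, ]
    solvent <- sub$solvent[1]
    veh <- rates[rates$role == "vehicle" & rates$solvent == solvent, ]
    dat <- dplyr::bind_rows(
      tibble(concentration_uM = sub$concentration_uM, y = sub$normalized_rate),
      tibble(concentration_uM = 0, y = veh$normalized_rate)
    )
    dat$group <- formatC(dat$concentration_uM, format = "g", digits = 15)
    n_conc <- length(unique(sub$concentration_uM))

    base <- tibble(
      compound = cmp, solvent = solvent, n_wells = nrow(sub), n_conc = n_conc,
      status = "unevaluable", anova_F = NA_real_, anova_p = NA_real_,
      significant = FALSE, fit_converged = FALSE, ic50_uM = NA_real_,
      ic50_label = "n.s.", A1 = NA_real_, A2 = NA_real_, x0 = NA_real_,
      dx = NA_real_, residual_ss = NA_real_,
      fit = list(NULL), tukey = list(NULL)
    )
    group_sizes <- table(dat$group)
    if (n_conc < 2 || nrow(veh) < 2 || any(group_sizes < 2)) return(base)

    an <- one_way_anova(dat, y, group)
    tk <- tukey_hsd(dat, y, group, alpha = alpha)
    veh_label <- formatC(0, format = "g", digits = 15)
    tk_veh <- tk[tk$group_i == veh_label | tk$group_j == veh_label, ]

    fit <- tryCatch(fit_boltzmann(dat, concentration_uM, y),
                    spheroscreen_fit_error = function(e) NULL)
    converged <- !is.null(fit) && fit$converged
    significant <- is.finite(an$statistic) && an$p_value < alpha
    report_ic50 <- significant && converged

    out <- base
    out$status <- if (report_ic50) "ok" else "n.s."
    out$anova_F <- an$statistic
    out$anova_p <- an$p_value
    out$significant <- significant
    out$fit_converged <- converged
    out$tukey <- list(tk_veh)
    if (converged) {
      out$A1 <- fit$coef[["A1"]]
      out$A2 <- fit$coef[["A2"]]
      out$x0 <- fit$coef[["x0"]]
      out$dx <- fit$coef[["dx"]]
      out$residual_ss <- fit$residual_ss
      out$fit <- list(fit)
    }
    if (report_ic50) {
      out$ic50_uM <- fit$ic50_uM
      out$ic50_label <- formatC(fit$ic50_uM, format = "g", digits = 4)
    }
    out
  })
}

#' Assay quality: Z' between vehicle and positive-control wells
#'
#' Computes the Z'-factor on normalized contraction rates between the
#' positive-control wells (e.g. saturating detergent dose) and the vehicle
#' wells of the same solvent group.
#'
#' @param rates Normalized rates tibble from [normalize_rates()].
#' @return A one-row tibble: `z_prime`, `n_pos`, `n_veh`, `mean_pos`,
#'   `mean_veh`.
#' @export
assay_quality <- function(rates) {
  pos <- rates[rates$role == "positive_control", ]
  if (nrow(pos) == 0) {
    stop_spheroscreen("no positive_control wells in rates", "spheroscreen_validation_error")
  }
  solvent <- pos$solvent[1]
  veh <- rates[rates$role == "vehicle" & rates$solvent == solvent, ]
  tibble(
    z_prime = z_prime(pos$normalized_rate, veh$normalized_rate),
    n_pos = nrow(pos), n_veh = nrow(veh),
    mean_pos = mean(pos$normalized_rate), mean_veh = mean(veh$normalized_rate)
  )
}
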