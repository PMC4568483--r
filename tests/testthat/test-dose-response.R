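boltzmann_f <- function(x, A1, A2, x0, dx) A2 + (A1 - A2) / (1 + exp((x - x0) / dx))

test_that("noiseless Boltzmann data are recovered to 1e-6 relative", {
  true <- list(A1 = 1, A2 = 0, x0 = log10(82.8), dx = 0.3)
  conc <- rep(10^seq(0, 3, length.out = 7), each = 3)
  d <- tibble::tibble(conc = conc,
                      y = boltzmann_f(log10(conc), true$A1, true$A2, true$x0, true$dx))
  fit <- fit_boltzmann(d, conc, y)
  expect_true(fit$converged)
  expect_equal(fit$coef[["A1"]], true$A1, tolerance = 1e-6)
  expect_equal(fit$coef[["A2"]], true$A2, tolerance = 1e-6)
  expect_equal(fit$coef[["x0"]], true$x0, tolerance = 1e-6)
  expect_equal(fit$coef[["dx"]], true$dx, tolerance = 1e-6)
  expect_equal(ic50(fit), 82.8, tolerance = 1e-5)

  td <- tidy(fit)
  expect_equal(td$term, c("A1", "A2", "x0", "dx"))
  expect_equal(glance(fit)$ic50_uM, 82.8, tolerance = 1e-5)
})

test_that("noisy fits agree with a dense grid-search oracle", {
  true <- list(A1 = 1, A2 = 0, x0 = log10(82.8), dx = 0.3)
  conc <- rep(10^seq(0, 3, length.out = 7), each = 3)
  x <- log10(conc)
  withr::with_seed(101, {
    for (i in 1:5) {
      y <- boltzmann_f(x, true$A1, true$A2, true$x0, true$dx) + rnorm(length(x), 0, 0.05)
      fit <- fit_boltzmann(tibble::tibble(conc = conc, y = y), conc, y)
      expect_true(fit$converged)
      oracle <- boltzmann_grid_oracle(x, y,
                                      x0_grid = seq(-0.5, 3.5, length.out = 161),
                                      dx_grid = seq(0.05, 1.5, length.out = 59))
      # the continuous optimizer must do at least as well as the grid
      expect_lte(fit$residual_ss, oracle$ss + 1e-8)
      expect_equal(fit$coef[["x0"]], oracle$x0, tolerance = 0.05)
      expect_lt(abs(log10(ic50(fit) / 82.8)), 0.1)
    }
  })
})

test_that("vehicle points anchor one decade below the lowest dose", {
  conc <- c(0, 0, 10, 32, 100, 320)
  y <- c(1, 1.02, 0.9, 0.6, 0.3, 0.1)
  fit <- fit_boltzmann(tibble::tibble(conc = conc, y = y), conc, y)
  expect_equal(sort(unique(fit$data$x))[1], 0) # log10(10) - 1
  fit2 <- fit_boltzmann(tibble::tibble(conc = conc, y = y), conc, y,
                        anchor_vehicle = FALSE)
  expect_equal(fit2$n_points, 4)
})

test_that("degenerate dose-response inputs are refused", {
  d <- tibble::tibble(conc = c(1, 10, 100, 1000), y = c(1, 1, 1, 1))
  expect_error(fit_boltzmann(d, conc, y), class = "spheroscreen_fit_error")
  d2 <- tibble::tibble(conc = c(1, 10, 100), y = c(1, 0.5, 0.1))
  expect_error(fit_boltzmann(d2, conc, y), class = "spheroscreen_fit_error")
})

test_that("IC50 reading of the fit is the transition midpoint", {
  fit <- structure(list(coef = c(A1 = 1, A2 = 0, x0 = 2, dx = 0.3),
                        converged = TRUE), class = "boltzmann_fit")
  expect_equal(ic50(fit), 100)
  fit$coef[["x0"]] <- log10(281.8)
  expect_equal(ic50(fit), 281.8, tolerance = 1e-9)
  # midpoint response sits halfway between the asymptotes
  expect_equal(boltzmann_f(log10(281.8), 1, 0, log10(281.8), 0.3), 0.5)

  # non-convergence is signalled distinctly from a fit error
  bad <- structure(list(coef = c(A1 = NA, A2 = NA, x0 = NA, dx = NA),
                        converged = FALSE), class = "boltzmann_fit")
  expect_error(ic50(bad), class = "spheroscreen_not_converged")
})

test_that("Z'-factor matches hand-computed values and its invariances", {
  expect_equal(z_prime(c(0.9, 1.0, 1.1), c(-0.1, 0, 0.1)), 0.4, tolerance = 1e-12)
  # zero-variance limit
  expect_equal(z_prime(c(1, 1, 1), c(0, 0, 0)), 1)
  # affine invariance
  withr::with_seed(7, {
    pos <- rnorm(8, 1, 0.05)
    neg <- rnorm(8, 0.2, 0.04)
    z <- z_prime(pos, neg)
    expect_lte(z, 1)
    expect_equal(z_prime(3 * pos - 2, 3 * neg - 2), z, tolerance = 1e-12)
    expect_equal(z_prime(-pos, -neg), z, tolerance = 1e-12)
  })
  expect_error(z_prime(c(1, 1), c(1, 1)),
               class = "spheroscreen_undefined_separation")
  expect_error(z_prime(1, c(0, 0)), class = "spheroscreen_validation_error")
})

test_that("one-way ANOVA matches hand-computed sums of squares", {
  d <- tibble::tibble(y = c(1, 2, 3, 2, 3, 4), g = rep(c("a", "b"), each = 3))
  res <- one_way_anova(d, y, g)
  # SSB = 1.5 (df 1), SSW = 4 (df 4) -> F = 1.5
  expect_equal(res$statistic, 1.5, tolerance = 1e-12)
  expect_equal(res$df_between, 1)
  expect_equal(res$df_within, 4)
  expect_equal(res$p_value, pf(1.5, 1, 4, lower.tail = FALSE), tolerance = 1e-12)

  # identical groups
  same <- tibble::tibble(y = rep(c(1, 2, 3), 2), g = rep(c("a", "b"), each = 3))
  res2 <- one_way_anova(same, y, g)
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p_value, 1)

  # enormous separation
  far <- tibble::tibble(y = c(rnorm(5), rnorm(5) + 1000), g = rep(c("a", "b"), each = 5))
  expect_lt(one_way_anova(far, y, g)$p_value, 1e-10)

  expect_error(one_way_anova(tibble::tibble(y = c(1, 2, 3), g = c("a", "a", "b")), y, g),
               class = "spheroscreen_validation_error")
})

test_that("ANOVA F matches a brute-force decomposition on random fixtures", {
  withr::with_seed(11, {
    for (i in 1:30) {
      k <- sample(2:5, 1)
      ns <- sample(2:8, k, replace = TRUE)
      y <- rnorm(sum(ns), mean = rep(runif(k, 0, 2), ns))
      g <- rep(letters[1:k], ns)
      res <- one_way_anova(tibble::tibble(y = y, g = g), y, g)
      # brute force
      gm <- mean(y)
      ssb <- sum(ns * (tapply(y, g, mean) - gm)^2)
      ssw <- sum((y - rep(tapply(y, g, mean), ns))^2)
      f_oracle <- (ssb / (k - 1)) / (ssw / (sum(ns) - k))
      expect_equal(res$statistic, f_oracle, tolerance = 1e-10)
    }
  })
})

test_that("Tukey HSD flags exactly the shifted group and matches base R", {
  withr::with_seed(3, {
    y <- c(rnorm(6, 0, 1), rnorm(6, 0, 1), rnorm(6, 10, 1))
    g <- rep(c("a", "b", "c"), each = 6)
    d <- tibble::tibble(y = y, g = g)
    tk <- tukey_hsd(d, y, g)
    expect_equal(nrow(tk), 3)
    sig <- tk$significant
    names(sig) <- paste(tk$group_i, tk$group_j)
    expect_false(sig[["a b"]])
    expect_true(sig[["a c"]])
    expect_true(sig[["b c"]])
    # p-values agree with stats::TukeyHSD
    base_tk <- TukeyHSD(aov(y ~ g))$g
    expect_equal(sort(tk$p_value), sort(unname(base_tk[, "p adj"])),
                 tolerance = 1e-8)
  })
})

test_that("two-group Tukey decisions coincide with the pooled t-test", {
  withr::with_seed(19, {
    agree <- 0
    n_fix <- 200
    for (i in seq_len(n_fix)) {
      n1 <- sample(3:8, 1)
      n2 <- sample(3:8, 1)
      shift <- sample(c(0, 0.5, 1, 2), 1)
      y <- c(rnorm(n1), rnorm(n2) + shift)
      g <- rep(c("a", "b"), c(n1, n2))
      tk <- tukey_hsd(tibble::tibble(y = y, g = g), y, g, alpha = 0.05)
      tt <- t.test(y ~ g, var.equal = TRUE)
      if (tk$significant[1] == (tt$p.value < 0.05)) agree <- agree + 1
    }
    expect_equal(agree, n_fix)
  })
})
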