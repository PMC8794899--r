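make_table <- function(values_by_method, raters = 1) {
  purrr::imap_dfr(values_by_method, function(v, m) {
    tidyr::expand_grid(
      specimen_id = sprintf("S%02d", seq_along(v)),
      rater_id = sprintf("R%d", seq_len(raters))
    ) |>
      dplyr::mutate(method = m, cdl_mm = v[as.integer(substr(specimen_id, 2, 3))])
  })
}

test_that("the per-method summary computes means, SDs and coverage correctly", {
  tab <- make_table(list(ref = c(40, 42, 44)))
  s <- summarize_methods(tab)
  expect_equal(s$mean_cdl, 42)
  expect_equal(s$sd_cdl, 2)
  tab2 <- make_table(list(m = c(31.5, 31.5)))
  s2 <- summarize_methods(tab2)
  expect_equal(s2$mean_cc, 100)
  expect_equal(s2$mean_ia, 900)
})

test_that("coverage is averaged per specimen (mean of ratios) and IA = 9 x CC exactly", {
  tab <- make_table(list(a = c(35, 40, 47), b = c(38, 44, 41)))
  s <- summarize_methods(tab)
  expect_equal(s$mean_cc[s$method == "a"], mean(31.5 / c(35, 40, 47) * 100))
  expect_false(isTRUE(all.equal(
    s$mean_cc[s$method == "a"], 31.5 / mean(c(35, 40, 47)) * 100
  )))
  expect_identical(s$mean_ia, 9 * s$mean_cc)
  expect_identical(s$sd_ia, 9 * s$sd_cc)
})

test_that("summarize is invariant to row order", {
  tab <- make_table(list(a = c(35, 40, 47), ref = c(38, 44, 41)))
  s1 <- summarize_methods(tab)
  s2 <- summarize_methods(tab[rev(seq_len(nrow(tab))), ])
  expect_equal(s1, s2)
})

test_that("one-way ANOVA: degrees of freedom, degenerate case, t-squared identity", {
  # 7 groups of 20 give the (6, 133) decomposition
  tab <- withr::with_seed(1, make_table(setNames(
    lapply(1:7, function(i) rnorm(20, 40 + i, 2)), paste0("m", 1:7)
  )))
  a <- anova_methods(tab)
  expect_equal(a$df_between, 6)
  expect_equal(a$df_within, 133)
  # identical groups: F defined as 0, p = 1
  same <- make_table(list(a = c(40, 41, 42), b = c(40, 41, 42)))
  same$cdl_mm <- 41
  a0 <- anova_methods(same)
  expect_equal(a0$statistic, 0)
  expect_equal(a0$p_value, 1)
  # two groups: F equals the squared pooled-variance t statistic
  x <- c(39.1, 41.2, 40.7, 43.0)
  y <- c(42.2, 44.8, 43.9, 45.1, 41.7)
  two <- make_table(list(gx = x, gy = y))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(anova_methods(two)$statistic, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(anova_methods(two)$p_value, tt$p.value, tolerance = 1e-9)
})

test_that("Dunnett with a single comparison reduces to the two-sample t-test", {
  x <- c(43.1, 41.2, 44.7, 42.0, 45.3)
  y <- c(38.2, 36.8, 40.1, 37.5, 39.0)
  tab <- make_table(list(reference = x, m1 = y))
  d <- dunnett_vs_control(tab)
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(d$p_adjusted, tt$p.value, tolerance = 1e-6)
  expect_equal(d$mean_difference, mean(x) - mean(y), tolerance = 1e-12)
  expect_equal(c(d$ci_lo, d$ci_hi), as.numeric(tt$conf.int), tolerance = 1e-6)
})

test_that("Dunnett-adjusted p-values dominate the unadjusted t-test p-values", {
  tab <- withr::with_seed(5, make_table(setNames(
    lapply(1:5, function(i) rnorm(12, 42 - 0.5 * i, 2)), c("reference", paste0("m", 1:4))
  )))
  d <- dunnett_vs_control(tab)
  ref <- tab$cdl_mm[tab$method == "reference"]
  for (m in d$method) {
    p_raw <- t.test(ref, tab$cdl_mm[tab$method == m], var.equal = TRUE)$p.value
    expect_gte(d$p_adjusted[d$method == m] + 1e-12, p_raw)
  }
  expect_true(all(d$ci_lo <= d$mean_difference & d$mean_difference <= d$ci_hi))
})

test_that("Dunnett agrees with the multcomp reference implementation", {
  skip_if_not_installed("multcomp")
  tab <- withr::with_seed(8, make_table(setNames(
    lapply(1:4, function(i) rnorm(15, 40 + i / 2, 1.5)),
    c("reference", paste0("m", 1:3))
  )))
  d <- dunnett_vs_control(tab)
  df <- data.frame(
    y = tab$cdl_mm,
    g = factor(tab$method, levels = c("reference", paste0("m", 1:3)))
  )
  fit <- multcomp::glht(stats::aov(y ~ g, df), linfct = multcomp::mcp(g = "Dunnett"))
  ms <- summary(fit)
  mc_p <- as.numeric(ms$test$pvalues)
  mc_est <- -as.numeric(ms$test$coefficients) # multcomp uses method - control
  expect_equal(d$mean_difference, mc_est, tolerance = 1e-9)
  # both sides use quasi-Monte-Carlo multivariate-t integration
  expect_equal(d$p_adjusted, mc_p, tolerance = 2e-2)
  ci <- confint(fit)$confint
  expect_equal(d$ci_lo, -as.numeric(ci[, "upr"]), tolerance = 5e-3)
  expect_equal(d$ci_hi, -as.numeric(ci[, "lwr"]), tolerance = 5e-3)
})

test_that("Dunnett controls the familywise error rate across the null family", {
  # all-null simulation: 7 groups of 20; reject when any adjusted CI excludes 0,
  # i.e. when max |t| exceeds the simultaneous critical point
  k <- 7L
  n <- 20L
  reps <- 5000L
  tab0 <- make_table(setNames(lapply(1:k, function(i) rnorm(n)), paste0("g", 1:k)))
  crit <- attr(dunnett_vs_control(tab0, control = "g1"), "critical_value")
  fwer <- withr::with_seed(99, {
    hits <- 0L
    for (r in seq_len(reps)) {
      X <- matrix(rnorm(k * n), n, k)
      means <- colMeans(X)
      mse <- sum(sweep(X, 2, means)^2) / (k * n - k)
      tstat <- (means[1] - means[-1]) / sqrt(mse * 2 / n)
      if (max(abs(tstat)) > crit) hits <- hits + 1L
    }
    hits / reps
  })
  expect_gt(fwer, 0.05 - 0.015)
  expect_lt(fwer, 0.05 + 0.015)
})

test_that("Pearson correlation matches hand-computed values", {
  expect_equal(pearson_cor(1:10, 2 * (1:10))$r, 1)
  expect_equal(pearson_cor(1:10, -2 * (1:10) + 3)$r, -1)
  ct <- pearson_cor(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(ct$r, 0.6)
  expect_equal(ct$n, 4)
  expect_error(pearson_cor(c(1, 1, 1), c(1, 2, 3)), class = "cdlkit_degenerate")
  expect_error(pearson_cor(1:2, 2:3), class = "cdlkit_input")
})

test_that("dependent-correlation comparison: symmetry, monotonicity, guards", {
  expect_equal(compare_dependent_correlations(0.8, 0.8, 0.5, 20)$p_value, 1)
  expect_equal(compare_dependent_correlations(0.8, 0.8, 0.5, 20)$statistic, 0)
  gaps <- c(0.05, 0.1, 0.2, 0.3)
  p <- vapply(gaps, function(g) {
    compare_dependent_correlations(0.6 + g / 2, 0.6 - g / 2, 0.5, 20)$p_value
  }, numeric(1))
  expect_true(all(diff(p) < 0))
  expect_error(compare_dependent_correlations(1, 0.5, 0.3, 20), class = "cdlkit_domain")
  expect_error(compare_dependent_correlations(0.5, 0.4, 0.3, 3), class = "cdlkit_input")
})

test_that("dependent-correlation test holds its nominal size (simulation oracle)", {
  # trivariate normal with equal correlations of the shared variable: null true
  R <- matrix(c(1, 0.7, 0.7, 0.7, 1, 0.5, 0.7, 0.5, 1), 3, 3)
  L <- chol(R)
  n <- 20L
  reps <- 4000L
  rej <- withr::with_seed(31, {
    hits <- 0L
    for (r in seq_len(reps)) {
      X <- matrix(rnorm(3 * n), n, 3) %*% L
      cm <- cor(X)
      p <- compare_dependent_correlations(cm[1, 2], cm[1, 3], cm[2, 3], n)$p_value
      if (p < 0.05) hits <- hits + 1L
    }
    hits / reps
  })
  expect_gt(rej, 0.05 - 0.015)
  expect_lt(rej, 0.05 + 0.015)
})

test_that("ICC(2,1) matches its closed-form examples", {
  M <- cbind(r1 = c(1, 2, 3, 4, 5), r2 = c(1, 2, 3, 4, 5))
  expect_equal(icc_agreement(M)$icc, 1)
  M2 <- cbind(r1 = 1:5, r2 = 1:5 + 1)
  fit <- icc_agreement(M2)
  expect_equal(fit$msr, 5)
  expect_equal(fit$msc, 2.5)
  expect_equal(fit$mse, 0)
  expect_equal(fit$icc, 5 / 6)
  expect_error(icc_agreement(matrix(3, 6, 2)), class = "cdlkit_degenerate")
  expect_error(icc_agreement(matrix(rnorm(8), 4, 2)), class = "cdlkit_input")
})

test_that("ICC(2,1) agrees with a variance-components (REML) oracle", {
  skip_if_not_installed("lme4")
  tab <- withr::with_seed(12, {
    n <- 150
    spec <- rnorm(n, 0, 2)
    rater_eff <- c(0, 0.3)
    tidyr::expand_grid(specimen_id = seq_len(n), rater_id = 1:2) |>
      dplyr::mutate(cdl_mm = 42 + spec[specimen_id] + rater_eff[rater_id] + rnorm(n * 2, 0, 1))
  })
  fit <- icc_agreement(tab)
  lmm <- lme4::lmer(
    cdl_mm ~ 1 + (1 | specimen_id) + (1 | rater_id),
    data = tab,
    control = lme4::lmerControl(check.conv.singular = lme4::.makeCC("ignore", tol = 1e-4))
  )
  vc <- as.data.frame(lme4::VarCorr(lmm))
  v <- setNames(vc$vcov, vc$grp)
  icc_pop <- v[["specimen_id"]] / (v[["specimen_id"]] + v[["rater_id"]] + v[["Residual"]])
  expect_equal(fit$icc, unname(icc_pop), tolerance = 0.01)
})

test_that("reliability banding matches the published labels", {
  expect_equal(icc_category(0.43), "fair")
  expect_equal(icc_category(0.29), "poor")
  expect_equal(icc_category(0.71), "good")
  expect_equal(icc_category(0.87), "excellent")
  expect_equal(icc_category(0.94), "excellent")
  # band edges: 0.40 and 0.60 and 0.75 are inclusive lower edges
  expect_equal(icc_category(c(0.399, 0.40, 0.599, 0.60, 0.749, 0.75)),
    c("poor", "fair", "fair", "good", "good", "excellent"))
  expect_error(icc_category(1.2), class = "cdlkit_domain")
})
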