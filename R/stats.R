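#' Per-method summary of a measurement table
#'
#' Means and sample SDs of CDL per method, with the per-specimen cochlear
#' coverage and insertion angle computed before averaging (mean of ratios,
#' not ratio of means). The linearity IA = 9 x CC holds exactly for both the
#' means and the SDs of the summary.
#'
#' @param table Long measurement table: columns specimen_id, method, cdl_mm
#'   (rater_id optional; raters are averaged per specimen first).
#' @param electrode An [electrode_spec()].
#' @param theta_full Full-cochlea angle (degrees).
#' @return Tibble of class `cdl_summary`: method, n, mean_cdl, sd_cdl,
#'   mean_cc, sd_cc, mean_ia, sd_ia.
#' @export
summarize_methods <- function(table, electrode = electrode_spec(), theta_full = 900) {
  check_measurement_table(table)
  per_spec <- table |>
    dplyr::group_by(.data$method, .data$specimen_id) |>
    dplyr::summarise(cdl_mm = mean(.data$cdl_mm), .groups = "drop") |>
    dplyr::mutate(
      cc_percent = predict_cc(.data$cdl_mm, electrode),
      ia_deg = predict_ia(.data$cc_percent, theta_full)
    )
  out <- per_spec |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_cdl = mean(.data$cdl_mm), sd_cdl = sd(.data$cdl_mm),
      mean_cc = mean(.data$cc_percent), sd_cc = sd(.data$cc_percent),
      .groups = "drop"
    ) |>
    # IA is an exact linear image of CC, so its summary is derived, not
    # re-estimated: mean_ia = 9 x mean_cc and sd_ia = 9 x sd_cc identically
    dplyr::mutate(
      mean_ia = .data$mean_cc * (theta_full / 100),
      sd_ia = .data$sd_cc * (theta_full / 100)
    )
  if (any(out$n < 2L)) {
    warn("methods with fewer than 2 specimens have undefined SDs")
  }
  class(out) <- c("cdl_summary", class(out))
  out
}

check_measurement_table <- function(table) {
  need <- c("specimen_id", "method", "cdl_mm")
  if (!all(need %in% names(table))) {
    stop_cdl(
      paste("measurement table needs columns", paste(need, collapse = ", ")),
      "input"
    )
  }
  invisible(table)
}

#' One-way ANOVA across estimation methods
#'
#' Standard between/within decomposition of per-specimen CDLs across
#' methods (specimen-averaged over raters first if a rater column exists).
#'
#' @param table Long measurement table (or any df with a value and group
#'   column named by `value`/`group`).
#' @param value,group Column names.
#' @return List of class `cdl_anova`: statistic, df, p_value, and the
#'   groupwise decomposition.
#' @export
anova_methods <- function(table, value = "cdl_mm", group = "method") {
  x <- table[[value]]
  g <- factor(table[[group]])
  if (nlevels(g) < 2L) stop_cdl("need at least 2 groups", "input")
  if (any(tapply(x, g, length) < 2L)) stop_cdl("each group needs >= 2 values", "input")
  k <- nlevels(g)
  N <- length(x)
  gm <- mean(x)
  means <- tapply(x, g, mean)
  ns <- tapply(x, g, length)
  ss_b <- sum(ns * (means - gm)^2)
  ss_w <- sum((x - means[g])^2)
  df_b <- k - 1L
  df_w <- N - k
  if (ss_w == 0 && ss_b == 0) {
    f <- 0
    p <- 1
  } else {
    f <- (ss_b / df_b) / (ss_w / df_w)
    p <- pf(f, df_b, df_w, lower.tail = FALSE)
  }
  structure(
    list(
      statistic = f, df_between = df_b, df_within = df_w, p_value = p,
      ms_within = if (df_w > 0) ss_w / df_w else NA_real_,
      group_means = means, group_n = ns
    ),
    class = "cdl_anova"
  )
}

#' @export
print.cdl_anova <- function(x, ...) {
  cat(sprintf(
    "One-way ANOVA: F(%d, %d) = %.2f, %s\n",
    x$df_between, x$df_within, x$statistic, format_p(x$p_value)
  ))
  invisible(x)
}

#' Dunnett comparisons against a control method
#'
#' Two-sided Dunnett-adjusted comparisons of every method against the
#' control (the reference method), with simultaneous 95% confidence
#' intervals from the multivariate-t critical point over the k-1 contrasts
#' (equicorrelated for balanced designs; the general correlation structure
#' for unbalanced ones). Mean differences use the convention
#' control - method, so a method that underestimates the reference gets a
#' positive difference.
#'
#' @param table Long measurement table.
#' @param control Control (reference) label.
#' @param value,group Column names.
#' @param level Simultaneous confidence level.
#' @return Tibble of class `cdl_dunnett`: method, n, mean_difference, ci_lo,
#'   ci_hi, statistic, p_adjusted; attributes carry the ANOVA error df.
#' @export
dunnett_vs_control <- function(table, control = "reference",
                               value = "cdl_mm", group = "method",
                               level = 0.95) {
  x <- table[[value]]
  g <- factor(table[[group]])
  if (!control %in% levels(g)) stop_cdl("control group not present", "input")
  if (nlevels(g) < 2L) stop_cdl("need the control plus at least one group", "input")
  means <- tapply(x, g, mean)
  ns <- tapply(x, g, length)
  N <- length(x)
  k <- nlevels(g)
  df <- N - k
  mse <- sum((x - means[g])^2) / df
  others <- setdiff(levels(g), control)
  n0 <- ns[[control]]
  ni <- ns[others]
  se <- sqrt(mse * (1 / n0 + 1 / ni))
  diff_ <- means[[control]] - means[others]
  tstat <- diff_ / se
  lambda <- sqrt(ni / (ni + n0))
  corr <- tcrossprod(lambda)
  diag(corr) <- 1
  m <- length(others)
  # quasi-randomised multivariate-t integration: pin the seed locally so
  # reports are reproducible without touching the caller's RNG stream
  p_adj <- withr::with_seed(1L, vapply(abs(tstat), function(t0) {
    if (m == 1L) {
      2 * pt(-t0, df)
    } else {
      1 - mvtnorm::pmvt(
        lower = rep(-t0, m), upper = rep(t0, m),
        df = df, corr = corr
      )[1]
    }
  }, numeric(1)))
  crit <- withr::with_seed(1L, if (m == 1L) {
    qt(1 - (1 - level) / 2, df)
  } else {
    mvtnorm::qmvt(level, tail = "both.tails", df = df, corr = corr)$quantile
  })
  out <- tibble::tibble(
    method = others,
    n = as.integer(ni),
    mean_difference = as.numeric(diff_),
    ci_lo = as.numeric(diff_ - crit * se),
    ci_hi = as.numeric(diff_ + crit * se),
    statistic = as.numeric(tstat),
    p_adjusted = pmin(1, as.numeric(p_adj))
  )
  attr(out, "control") <- control
  attr(out, "df") <- df
  attr(out, "critical_value") <- crit
  attr(out, "level") <- level
  class(out) <- c("cdl_dunnett", class(out))
  out
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y Numeric vectors (n >= 3, finite, non-constant).
#' @return Tibble of class `cdl_cor`: r, statistic, df, p_value, n.
#' @export
pearson_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3L) stop_cdl("need at least 3 paired values", "input")
  if (sd(x) == 0 || sd(y) == 0) stop_cdl("zero variance: correlation undefined", "degenerate")
  ct <- cor.test(x, y, method = "pearson")
  out <- tibble::tibble(
    r = unname(ct$estimate),
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p_value = ct$p.value,
    n = length(x)
  )
  class(out) <- c("cdl_cor", class(out))
  out
}

#' Compare two dependent correlations sharing one variable
#'
#' Hotelling-Williams test for whether cor(j,k) differs from cor(j,h) when
#' both correlations are computed on the same n subjects and share the
#' variable j (here: the reference CDL). The statistic is t-distributed with
#' n - 3 degrees of freedom under the null of equal correlations.
#'
#' @param r_jk,r_jh The two correlations sharing variable j.
#' @param r_kh Correlation between the two non-shared variables.
#' @param n Sample size (>= 4).
#' @return Tibble: statistic, df, p_value.
#' @export
compare_dependent_correlations <- function(r_jk, r_jh, r_kh, n) {
  rs <- c(r_jk, r_jh, r_kh)
  if (any(abs(rs) >= 1)) stop_cdl("correlations must lie strictly inside (-1, 1)", "domain")
  if (n < 4L) stop_cdl("need n >= 4", "input")
  detR <- 1 - r_jk^2 - r_jh^2 - r_kh^2 + 2 * r_jk * r_jh * r_kh
  rbar <- (r_jk + r_jh) / 2
  num <- (r_jk - r_jh) * sqrt((n - 1) * (1 + r_kh))
  den <- sqrt(2 * ((n - 1) / (n - 3)) * detR + rbar^2 * (1 - r_kh)^3)
  tstat <- num / den
  tibble::tibble(
    statistic = tstat,
    df = n - 3,
    p_value = 2 * pt(-abs(tstat), n - 3)
  )
}

#' Inter-rater agreement: ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement intraclass
#' correlation from the two-way ANOVA mean squares:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#'
#' @param ratings Long tibble (specimen_id, rater_id, value column named by
#'   `value`) or a wide matrix/data frame of specimens x raters.
#' @param value Value column for long input.
#' @param bands Reliability banding passed to [icc_category()].
#' @return List of class `cdl_icc`: icc, model, category, mean squares, n, k.
#' @export
icc_agreement <- function(ratings, value = "cdl_mm", bands = icc_bands_default()) {
  M <- ratings_matrix(ratings, value)
  n <- nrow(M)
  k <- ncol(M)
  if (n < 5L) stop_cdl("need at least 5 specimens", "input")
  if (k < 2L) stop_cdl("need at least 2 raters", "input")
  if (anyNA(M)) stop_cdl("ratings must be complete", "input")
  gm <- mean(M)
  row_m <- rowMeans(M)
  col_m <- colMeans(M)
  ss_total <- sum((M - gm)^2)
  if (ss_total == 0) stop_cdl("zero total variance: ICC undefined", "degenerate")
  msr <- k * sum((row_m - gm)^2) / (n - 1)
  msc <- n * sum((col_m - gm)^2) / (k - 1)
  sse <- ss_total - k * sum((row_m - gm)^2) - n * sum((col_m - gm)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  structure(
    list(
      icc = icc, model = "ICC(2,1) two-way random, absolute agreement",
      category = icc_category(icc, bands),
      msr = msr, msc = msc, mse = mse, n = n, k = k
    ),
    class = "cdl_icc"
  )
}

ratings_matrix <- function(ratings, value) {
  if (is.matrix(ratings)) return(ratings)
  if (all(c("specimen_id", "rater_id") %in% names(ratings))) {
    wide <- tidyr::pivot_wider(
      dplyr::select(ratings, "specimen_id", "rater_id", dplyr::all_of(value)),
      names_from = "rater_id", values_from = dplyr::all_of(value)
    )
    return(as.matrix(wide[, -1]))
  }
  as.matrix(ratings)
}

#' @export
print.cdl_icc <- function(x, ...) {
  cat(sprintf("%s: ICC = %.3f (%s)\n", x$model, x$icc, x$category))
  invisible(x)
}

#' Default reliability bands
#'
#' Cutpoints of the poor / fair / good / excellent banding: below 0.40 poor,
#' 0.40-0.59 fair, 0.60-0.74 good, 0.75 and above excellent.
#'
#' @return Named numeric vector of lower band edges.
#' @export
icc_bands_default <- function() {
  c(poor = -Inf, fair = 0.40, good = 0.60, excellent = 0.75)
}

#' Reliability category of an ICC
#'
#' @param icc ICC value(s), each <= 1.
#' @param bands Named lower band edges, see [icc_bands_default()].
#' @return Character category per value.
#' @export
icc_category <- function(icc, bands = icc_bands_default()) {
  if (any(icc > 1)) stop_cdl("ICC cannot exceed 1", "domain")
  labels <- names(bands)
  idx <- vapply(icc, function(v) max(which(v >= bands)), integer(1))
  labels[idx]
}

format_p <- function(p, digits = 3) {
  ifelse(p < 0.001, "p < 0.001", sprintf("p = %.*f", digits, p))
}
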