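#' Build a structured method-comparison report
#'
#' Assembles the summary table, ANOVA, Dunnett listing, correlation matrix
#' against the reference, and inter-rater reliability into one object that
#' serialises to JSON and renders to Markdown. The report head flags the
#' two documented analysis assumptions (ICC variant and dependent-correlation
#' test choice).
#'
#' @param summary A [summarize_methods()] result.
#' @param anova A [anova_methods()] result.
#' @param dunnett A [dunnett_vs_control()] result.
#' @param correlations Tibble (method, r, p_value, n), e.g. from
#'   [correlate_with_reference()].
#' @param reliability Tibble (method, icc, category), e.g. from
#'   [reliability_by_method()].
#' @return A list of class `cdl_report`.
#' @export
build_report <- function(summary, anova, dunnett, correlations = NULL,
                         reliability = NULL) {
  missing <- c(
    if (is.null(summary)) "summary",
    if (is.null(anova)) "anova",
    if (is.null(dunnett)) "dunnett"
  )
  if (length(missing)) {
    stop_cdl(paste("missing report stages:", paste(missing, collapse = ", ")), "input")
  }
  structure(
    list(
      assumptions = c(
        "ICC variant: ICC(2,1) two-way random effects, absolute agreement, single measurement",
        "Dependent-correlation comparison: Hotelling-Williams t"
      ),
      summary = summary,
      anova = anova,
      dunnett = dunnett,
      correlations = correlations,
      reliability = reliability
    ),
    class = "cdl_report"
  )
}

#' Correlations of each method with the reference
#'
#' @param table Long measurement table including `reference` rows.
#' @param control Reference label.
#' @return Tibble: method, r, statistic, df, p_value, n.
#' @export
correlate_with_reference <- function(table, control = "reference") {
  check_measurement_table(table)
  per_spec <- table |>
    dplyr::group_by(.data$method, .data$specimen_id) |>
    dplyr::summarise(cdl_mm = mean(.data$cdl_mm), .groups = "drop")
  wide <- tidyr::pivot_wider(per_spec, names_from = "method", values_from = "cdl_mm")
  if (!control %in% names(wide)) stop_cdl("no reference rows present", "input")
  methods <- setdiff(names(wide), c("specimen_id", control))
  purrr::map_dfr(methods, function(m) {
    ct <- pearson_cor(wide[[control]], wide[[m]])
    dplyr::bind_cols(tibble::tibble(method = m), ct)
  })
}

#' Inter-rater reliability per method
#'
#' @param table Long measurement table with a rater_id column.
#' @return Tibble: method, icc, category.
#' @export
reliability_by_method <- function(table) {
  check_measurement_table(table)
  if (!"rater_id" %in% names(table)) stop_cdl("table has no rater_id column", "input")
  purrr::map_dfr(split(table, table$method), function(d) {
    fit <- icc_agreement(d)
    tibble::tibble(method = d$method[1], icc = fit$icc, category = fit$category)
  })
}

#' @export
print.cdl_report <- function(x, ...) {
  cat(format_report_md(x), sep = "\n")
  invisible(x)
}

#' Render a report to Markdown lines
#'
#' @param report A `cdl_report`.
#' @return Character vector of Markdown lines.
#' @export
format_report_md <- function(report) {
  s <- report$summary
  lines <- c(
    "# CDL method comparison",
    "",
    paste0("> Assumption: ", report$assumptions),
    "",
    "## Per-method summary",
    "",
    "| method | n | mean CDL (mm) | SD | mean CC (%) | SD | mean IA (deg) | SD |",
    "|---|---|---|---|---|---|---|---|",
    sprintf(
      "| %s | %d | %.1f | %.1f | %.1f | %.1f | %.1f | %.1f |",
      s$method, s$n, s$mean_cdl, s$sd_cdl, s$mean_cc, s$sd_cc, s$mean_ia, s$sd_ia
    ),
    "",
    sprintf(
      "## ANOVA\n\nF(%d, %d) = %.2f, %s",
      report$anova$df_between, report$anova$df_within,
      report$anova$statistic, format_p(report$anova$p_value)
    ),
    "",
    sprintf("## Dunnett vs %s", attr(report$dunnett, "control") %||% "control"),
    "",
    "| method | mean difference (mm) | 95% CI | p (adj) |",
    "|---|---|---|---|",
    sprintf(
      "| %s | %.1f | %.1f to %.1f | %s |",
      report$dunnett$method, report$dunnett$mean_difference,
      report$dunnett$ci_lo, report$dunnett$ci_hi,
      format_p(report$dunnett$p_adjusted)
    )
  )
  if (!is.null(report$correlations)) {
    lines <- c(
      lines, "", "## Correlation with reference", "",
      "| method | r | p |", "|---|---|---|",
      sprintf(
        "| %s | %.2f | %s |",
        report$correlations$method, report$correlations$r,
        format_p(report$correlations$p_value)
      )
    )
  }
  if (!is.null(report$reliability)) {
    lines <- c(
      lines, "", "## Inter-rater reliability", "",
      "| method | ICC | category |", "|---|---|---|",
      sprintf(
        "| %s | %.2f | %s |",
        report$reliability$method, report$reliability$icc,
        report$reliability$category
      )
    )
  }
  lines
}

#' Write a report to disk
#'
#' Writes `report.json` and `report.md` (plus the summary and Dunnett tables
#' as CSV) into a directory.
#'
#' @param report A `cdl_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  payload <- list(
    assumptions = report$assumptions,
    summary = report$summary,
    anova = report$anova[c("statistic", "df_between", "df_within", "p_value")],
    dunnett = as.data.frame(report$dunnett),
    correlations = report$correlations,
    reliability = report$reliability
  )
  jsonlite::write_json(
    payload, file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
  )
  writeLines(format_report_md(report), file.path(dir, "report.md"))
  readr::write_csv(tibble::as_tibble(report$summary), file.path(dir, "summary.csv"))
  readr::write_csv(tibble::as_tibble(report$dunnett), file.path(dir, "dunnett.csv"))
  invisible(dir)
}
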