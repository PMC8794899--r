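# broom-style tidiers for the fitted/statistical objects.

#' Tidy a CDL ANOVA
#'
#' @param x A [anova_methods()] result.
#' @param ... Unused.
#' @return One-row tibble: term, statistic, df, df_residual, p.value.
#' @method tidy cdl_anova
#' @export
tidy.cdl_anova <- function(x, ...) {
  tibble::tibble(
    term = "method",
    statistic = x$statistic,
    df = x$df_between,
    df.residual = x$df_within,
    p.value = x$p_value
  )
}

#' @rdname tidy.cdl_anova
#' @method glance cdl_anova
#' @export
glance.cdl_anova <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic,
    df = x$df_between,
    df.residual = x$df_within,
    p.value = x$p_value,
    ms.within = x$ms_within,
    n.groups = length(x$group_means)
  )
}

#' Tidy a Dunnett comparison table
#'
#' @param x A [dunnett_vs_control()] result.
#' @param ... Unused.
#' @return Tibble with one row per comparison (contrast, estimate, conf.low,
#'   conf.high, statistic, adj.p.value).
#' @method tidy cdl_dunnett
#' @export
tidy.cdl_dunnett <- function(x, ...) {
  tibble::tibble(
    contrast = paste(attr(x, "control"), "-", x$method),
    estimate = x$mean_difference,
    conf.low = x$ci_lo,
    conf.high = x$ci_hi,
    statistic = x$statistic,
    df = attr(x, "df"),
    adj.p.value = x$p_adjusted
  )
}

#' Tidy an inter-rater reliability result
#'
#' @param x An [icc_agreement()] result.
#' @param ... Unused.
#' @return One-row tibble: estimate, model, category, and the mean squares.
#' @method tidy cdl_icc
#' @export
tidy.cdl_icc <- function(x, ...) {
  tibble::tibble(
    estimate = x$icc,
    model = x$model,
    category = x$category,
    msr = x$msr, msc = x$msc, mse = x$mse,
    n = x$n, k = x$k
  )
}

#' Tidy an insertion simulation
#'
#' @param x A [simulate_insertion()] result.
#' @param ... Unused.
#' @return The per-contact tibble with the scalar angles attached.
#' @method tidy insertion_result
#' @export
tidy.insertion_result <- function(x, ...) {
  dplyr::mutate(
    x$contacts,
    ia_contact_span = x$ia_contact_span,
    ia_tip_from_rw = x$ia_tip_from_rw,
    full_insertion = x$full_insertion
  )
}

#' @rdname tidy.insertion_result
#' @method glance insertion_result
#' @export
glance.insertion_result <- function(x, ...) {
  tibble::tibble(
    ia_contact_span = x$ia_contact_span,
    ia_tip_from_rw = x$ia_tip_from_rw,
    insertion_depth_mm = x$insertion_depth_mm,
    trajectory_length_mm = x$trajectory_length_mm,
    full_insertion = x$full_insertion,
    wall_offset_mm = x$wall_offset_mm
  )
}
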