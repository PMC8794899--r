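# ggplot2 visualisations for the main result types.

#' Plot an aligned cochlea
#'
#' xy-projection of the canonical-frame lateral wall, coloured by height.
#'
#' @param object An `aligned_cochlea`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot aligned_cochlea
#' @export
autoplot.aligned_cochlea <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$x, y = .data$y, colour = .data$z)) +
    ggplot2::geom_path(linewidth = 0.3, colour = "grey70") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "x (mm)", y = "y (mm)", colour = "z (mm)",
      title = "Aligned lateral wall (canonical modiolar frame)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a per-method summary
#'
#' Mean CDL per method with +-1 SD whiskers, the Table-1-style view.
#'
#' @param object A [summarize_methods()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cdl_summary
#' @export
autoplot.cdl_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$method, y = .data$mean_cdl)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_cdl - .data$sd_cdl,
      ymax = .data$mean_cdl + .data$sd_cdl
    )) +
    ggplot2::labs(x = NULL, y = "CDL (mm)", title = "CDL by estimation method") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Forest plot of Dunnett comparisons
#'
#' @param object A [dunnett_vs_control()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cdl_dunnett
#' @export
autoplot.cdl_dunnett <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_difference, y = .data$method)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_lo, xmax = .data$ci_hi)) +
    ggplot2::labs(
      x = sprintf(
        "%s - method (mm), simultaneous %.0f%% CI",
        attr(object, "control") %||% "control", 100 * (attr(object, "level") %||% 0.95)
      ),
      y = NULL, title = "Underestimation vs reference"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an insertion result
#'
#' Unwrapped contact angles from base to apex.
#'
#' @param object A [simulate_insertion()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot insertion_result
#' @export
autoplot.insertion_result <- function(object, ...) {
  ggplot2::ggplot(object$contacts, ggplot2::aes(x = .data$contact, y = .data$theta_deg)) +
    ggplot2::geom_line(colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = object$contacts$contact) +
    ggplot2::labs(
      x = "contact (1 = apical)", y = "unwrapped angle (deg)",
      title = sprintf(
        "Simulated insertion: IA %.0f deg (contact span), %.0f deg (tip)",
        object$ia_contact_span, object$ia_tip_from_rw
      )
    ) +
    ggplot2::theme_minimal()
}
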