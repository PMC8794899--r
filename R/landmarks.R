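#' Basal-turn landmark distances A, B and H
#'
#' The A-value is the basal-turn diameter: the xy-projected distance from the
#' round window, through the modiolar axis, to the opposite lateral wall
#' (the wall point at unwrapped angle 180 degrees). The B-value is the
#' wall-to-wall width perpendicular to the A line through the axis (the chord
#' between the wall points at 90 and 270 degrees). The H-value is the
#' cochlear height: the z-extent of the wall trajectory from basal turn to
#' apex.
#'
#' All three are measured on the fitted lateral-wall spline of an aligned
#' cloud, so they are invariant under rigid transforms of the input.
#'
#' @param x An `aligned_cochlea` or an `lw_spline` (angle-parameterised).
#' @param smoothing Spline smoothing when `x` is an aligned cloud
#'   (`"none"` for exact geometric clouds, `"gcv"` for noisy ones).
#' @return `measure_A`/`measure_B`/`measure_H` return a length in mm;
#'   `measure_basal_metrics` a one-row tibble with columns A_mm, B_mm, H_mm.
#' @export
measure_A <- function(x, smoothing = "none") {
  curve <- as_lw_curve(x, smoothing)
  if (curve$theta_range[2] < 180) {
    stop_cdl("cloud does not reach 180 degrees: A-value undefined", "measurement")
  }
  p0 <- eval_spline(curve, 0)
  p180 <- eval_spline(curve, 180)
  sqrt((p0$x - p180$x)^2 + (p0$y - p180$y)^2)
}

#' @rdname measure_A
#' @export
measure_B <- function(x, smoothing = "none") {
  curve <- as_lw_curve(x, smoothing)
  if (curve$theta_range[2] < 270) {
    stop_cdl("cloud does not reach 270 degrees: B-value undefined", "measurement")
  }
  p90 <- eval_spline(curve, 90)
  p270 <- eval_spline(curve, 270)
  sqrt((p90$x - p270$x)^2 + (p90$y - p270$y)^2)
}

#' @rdname measure_A
#' @export
measure_H <- function(x, smoothing = "none") {
  curve <- as_lw_curve(x, smoothing)
  if (diff(curve$theta_range) < 540) {
    warn("cloud spans less than 1.5 turns; apex (H-value) is poorly defined")
  }
  g <- seq(curve$theta_range[1], curve$theta_range[2], length.out = 2000L)
  z <- eval_spline(curve, g)$z
  diff(range(z))
}

#' @rdname measure_A
#' @export
measure_basal_metrics <- function(x, smoothing = "none") {
  curve <- as_lw_curve(x, smoothing)
  tibble::tibble(
    A_mm = measure_A(curve),
    B_mm = measure_B(curve),
    H_mm = measure_H(curve)
  )
}

as_lw_curve <- function(x, smoothing = "none") {
  if (inherits(x, "lw_spline")) {
    if (x$param != "angle") {
      stop_cdl("landmark measurement needs an angle-parameterised curve", "measurement")
    }
    return(x)
  }
  if (inherits(x, "aligned_cochlea")) {
    return(fit_lateral_wall_spline(x, smoothing = smoothing, param = "angle"))
  }
  stop_cdl("expected an aligned_cochlea or lw_spline", "input")
}
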