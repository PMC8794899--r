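#' Fit a 3D spline curve to the lateral wall
#'
#' Fits a parametric cubic spline through (or, with smoothing, near) the
#' aligned lateral-wall points. With `param = "angle"` (default) the curve is
#' parameterised by the unwrapped angle theta, which is the natural parameter
#' for a spiral and makes the angular coordinate map exact; `param = "chord"`
#' uses cumulative chordal length, appropriate for non-spiralling point sets
#' (e.g. a straight digitised segment).
#'
#' `smoothing = "none"` interpolates the points exactly and is the right
#' choice for noise-free geometry. The default `smoothing = "gcv"` fits a
#' cross-validated smoothing spline per coordinate, which is essential for
#' jittered or voxel-quantised clouds: an interpolating spline through points
#' whose spacing is comparable to the noise inflates arc length severely.
#'
#' @param aligned An [align_cochlea()] result.
#' @param smoothing `"gcv"` or `"none"`.
#' @param param `"angle"` or `"chord"`.
#' @return An object of class `lw_spline`.
#' @export
fit_lateral_wall_spline <- function(aligned,
                                    smoothing = c("gcv", "none"),
                                    param = c("angle", "chord")) {
  stopifnot(inherits(aligned, "aligned_cochlea"))
  smoothing <- match.arg(smoothing)
  param <- match.arg(param)
  pts <- aligned$points
  if (nrow(pts) < 4L) stop_cdl("spline fit needs at least 4 points", "insufficient_data")

  if (param == "angle") {
    o <- order(pts$theta)
    s <- pts$theta[o]
    M <- cbind(pts$x[o], pts$y[o], pts$z[o])
    # collapse exact duplicate parameter values (voxel bins, repeated digitising)
    if (anyDuplicated(s)) {
      grp <- match(s, unique(s))
      M <- apply(M, 2, function(col) tapply(col, grp, mean))
      s <- unique(s)
    }
    theta_range <- range(s)
  } else {
    M <- cbind(pts$x, pts$y, pts$z)
    s <- c(0, cumsum(sqrt(rowSums(diff(M)^2))))
    theta_range <- range(pts$theta)
  }
  if (length(s) < 4L) stop_cdl("spline fit needs at least 4 distinct points", "insufficient_data")

  fit1 <- function(y) {
    if (smoothing == "none") {
      f <- splinefun(s, y, method = "fmm")
      function(t, deriv = 0L) f(t, deriv = deriv)
    } else {
      sm <- tryCatch(
        suppressWarnings(smooth.spline(s, y, cv = FALSE)),
        error = function(e) NULL
      )
      if (is.null(sm)) {
        f <- splinefun(s, y, method = "fmm")
        function(t, deriv = 0L) f(t, deriv = deriv)
      } else {
        function(t, deriv = 0L) predict(sm, t, deriv = deriv)$y
      }
    }
  }

  curve <- structure(
    list(
      fx = fit1(M[, 1]), fy = fit1(M[, 2]), fz = fit1(M[, 3]),
      s_range = range(s),
      theta_range = theta_range,
      param = param,
      smoothing = smoothing,
      n_points = length(s),
      side = aligned$side
    ),
    class = "lw_spline"
  )
  if (param == "chord") {
    # monotone angle map theta(t) where available (spiralling clouds)
    th <- aligned$points$theta
    if (length(th) == length(pts$theta) && !is.unsorted(th, strictly = TRUE)) {
      curve$theta_of_s <- splinefun(s, th, method = "hyman")
      curve$s_of_theta <- splinefun(th, s, method = "hyman")
    }
  }
  curve
}

#' @export
print.lw_spline <- function(x, ...) {
  cat(sprintf(
    "<lw_spline> %s-parameterised, smoothing = %s, %d knots, theta %.1f..%.1f deg\n",
    x$param, x$smoothing, x$n_points, x$theta_range[1], x$theta_range[2]
  ))
  invisible(x)
}

curve_param_at_theta <- function(curve, theta) {
  if (curve$param == "angle") return(theta)
  if (is.null(curve$s_of_theta)) {
    stop_cdl("curve has no angular coordinate map", "domain")
  }
  curve$s_of_theta(theta)
}

#' Evaluate a lateral-wall spline
#'
#' @param curve An `lw_spline`.
#' @param theta Angles (degrees) at which to evaluate; for chord-parameterised
#'   curves without an angle map, interpreted as the chordal parameter (mm).
#' @return Tibble with columns theta, x, y, z.
#' @export
eval_spline <- function(curve, theta) {
  s <- curve_param_at_theta(curve, theta)
  tibble::tibble(
    theta = theta,
    x = curve$fx(s), y = curve$fy(s), z = curve$fz(s)
  )
}

curve_speed <- function(curve) {
  function(s) {
    sqrt(curve$fx(s, deriv = 1L)^2 + curve$fy(s, deriv = 1L)^2 + curve$fz(s, deriv = 1L)^2)
  }
}

#' Arc length along the lateral-wall spline
#'
#' Integrates the curve speed between two angular positions with composite
#' Gauss-Legendre quadrature (panels of at most 5 degrees, 15 nodes each;
#' absolute accuracy well below 1e-6 mm for these curves). The full-extent
#' arc length of an aligned, fitted cochlea is its 3D-measured CDL.
#'
#' @param curve An `lw_spline`.
#' @param theta_start,theta_end Angular range (degrees); defaults to the
#'   curve's full fitted range.
#' @return Arc length in mm.
#' @export
arc_length <- function(curve, theta_start = NULL, theta_end = NULL) {
  stopifnot(inherits(curve, "lw_spline"))
  default_range <- if (curve$param == "angle" || !is.null(curve$s_of_theta)) {
    curve$theta_range
  } else {
    curve$s_range
  }
  theta_start <- theta_start %||% default_range[1]
  theta_end <- theta_end %||% default_range[2]
  if (theta_end < theta_start) stop_cdl("theta_end must be >= theta_start", "domain")
  eps <- 1e-9
  if (curve$param == "angle") {
    rng <- curve$theta_range
    if (theta_start < rng[1] - eps || theta_end > rng[2] + eps) {
      stop_cdl("requested angles outside the fitted range", "domain")
    }
    a <- curve_param_at_theta(curve, theta_start)
    b <- curve_param_at_theta(curve, theta_end)
    panel <- 5
  } else {
    if (!is.null(curve$s_of_theta)) {
      a <- curve$s_of_theta(theta_start)
      b <- curve$s_of_theta(theta_end)
    } else {
      a <- theta_start
      b <- theta_end
    }
    if (a < curve$s_range[1] - eps || b > curve$s_range[2] + eps) {
      stop_cdl("requested range outside the fitted curve", "domain")
    }
    panel <- max((curve$s_range[2] - curve$s_range[1]) / 40, 1e-6)
  }
  if (b <= a) return(0)
  gauss_quad(curve_speed(curve), a, b, panel = panel)
}

#' Three-dimensional spline CDL of a point cloud
#'
#' Convenience wrapper: aligns the cloud, fits the spline, and returns the
#' full-extent arc length as a [cdl_estimate] row with method `"spline3D"`.
#'
#' @param cloud An `lw_cloud` (or data frame of x, y, z).
#' @param smoothing Passed to [fit_lateral_wall_spline()].
#' @return A `cdl_estimate` tibble (one row).
#' @export
cdl_spline3d <- function(cloud, smoothing = "gcv") {
  aligned <- align_cochlea(cloud)
  curve <- fit_lateral_wall_spline(aligned, smoothing = smoothing)
  new_cdl_estimate(
    cdl_mm = arc_length(curve),
    method = "spline3D",
    theta_deg = diff(curve$theta_range),
    surface = "lateral_wall"
  )
}
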