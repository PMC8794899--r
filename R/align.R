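#' Align a cochlear point cloud to the canonical modiolar frame
#'
#' Rigidly transforms a lateral-wall point cloud so that the modiolar axis
#' (the spiral axis) is the z-axis, the basal turn lies in the xy-plane
#' (mean z of the first 360 degrees is zero), and the round-window point sits
#' at angular coordinate 0. The unwrapped angle increases counterclockwise
#' about +z from base to apex; for a left ear the same frame is used (the
#' cloud is viewed "as a right ear"), which keeps every downstream
#' measurement side-agnostic.
#'
#' The axis and its position are found by an iterated harmonic regression:
#' the in-plane center is the first-harmonic component of the radius profile
#' r(theta) (with a cubic baseline and, for clouds spanning at least 540
#' degrees, envelope-modulated second harmonics that absorb basal-turn
#' ellipticity), and the axis tilt is the r*cos/r*sin component of the height
#' profile z(theta) over a piecewise-linear baseline. The procedure is a
#' fixed-point iteration: re-aligning an aligned cloud is the identity to
#' numerical precision, and all outputs are invariant under rigid transforms
#' of the input.
#'
#' @param cloud An [lateral_wall_cloud()] (or a data frame with x, y, z).
#' @param max_iter,tol Iteration control for the fixed point.
#' @return An object of class `aligned_cochlea` with elements
#'   `points` (tibble x, y, z, theta in insertion order),
#'   `transform` (list with `rotation` 3x3 and `translation` length-3 such
#'   that aligned = rotation %*% p + translation), and `side`.
#' @export
align_cochlea <- function(cloud, max_iter = 60L, tol = 1e-10) {
  if (!inherits(cloud, "lw_cloud")) cloud <- lateral_wall_cloud(cloud)
  P <- as.matrix(tibble::as_tibble(cloud)[, c("x", "y", "z")])
  if (nrow(P) < 10L) stop_cdl("alignment needs at least 10 points", "alignment")

  A <- diag(3) # accumulated right-multiplier: aligned = P %*% A + b
  b <- c(0, 0, 0)
  apply_rot <- function(Q) {
    P1 <<- P1 %*% Q
    A <<- A %*% Q
    b <<- as.vector(b %*% Q)
  }
  apply_shift <- function(d) {
    P1 <<- sweep(P1, 2, d)
    b <<- b - d
  }

  P1 <- P
  apply_shift(colMeans(P))
  ev <- eigen(crossprod(P1) / nrow(P1), symmetric = TRUE)
  if (ev$values[2] < 1e-12 * max(ev$values[1], 1e-300)) {
    stop_cdl("degenerate (collinear) cloud: spiral axis is ambiguous", "alignment")
  }
  R0 <- ev$vectors
  if (det(R0) < 0) R0[, 3] <- -R0[, 3]
  apply_rot(R0)

  flip_x <- diag(c(1, -1, -1)) # 180-degree rotation about x: reverses winding

  for (it in seq_len(max_iter)) {
    th <- unwrap_degrees(atan2(P1[, 2], P1[, 1]) * 180 / pi)
    if (th[length(th)] < th[1]) {
      apply_rot(flip_x)
      th <- unwrap_degrees(atan2(P1[, 2], P1[, 1]) * 180 / pi)
    }
    th <- th - th[1]
    span <- max(th) - min(th)
    if (it == 1L && span < 270) {
      stop_cdl("cloud spans less than 270 degrees of turn; axis is ill-determined", "alignment")
    }
    thr <- th * pi / 180
    tt <- thr / max(abs(thr))
    r <- sqrt(P1[, 1]^2 + P1[, 2]^2)
    # a residual tilt perturbs apical polar angles by ~ z * tilt / r, so the
    # tight apex destabilises the fit: estimate from the larger-radius turns
    sel <- r >= 0.2 * stats::quantile(r, 0.95)
    if (sum(sel) < 20L) sel <- rep(TRUE, length(r))
    # Baseline flexibility must stay below what can mimic a first harmonic:
    # over a single turn a cubic tracks one cosine cycle almost perfectly and
    # the center becomes ill-determined, so short spans get a linear baseline.
    # The second harmonics absorb basal-turn ellipticity so it cannot leak
    # into the first-harmonic (center) terms; for multi-turn clouds the
    # ellipticity fades apically, hence the tt envelopes.
    if (span >= 540) {
      base <- cbind(1, tt, tt^2, tt^3)
      env2 <- cbind(
        cos(2 * thr), cos(2 * thr) * tt, cos(2 * thr) * tt^2,
        sin(2 * thr), sin(2 * thr) * tt, sin(2 * thr) * tt^2
      )
    } else {
      base <- cbind(1, tt)
      env2 <- cbind(cos(2 * thr), sin(2 * thr))
    }
    X <- cbind(base, env2, cos(thr), sin(thr))
    # the regressors use angles relative to the first point, so the fitted
    # first-harmonic coefficients live in a basis rotated by its absolute
    # polar angle phi0; rotate them back before applying in x/y coordinates
    phi0 <- atan2(P1[1, 2], P1[1, 1])
    to_abs <- function(u, v) {
      c(u * cos(phi0) - v * sin(phi0), u * sin(phi0) + v * cos(phi0))
    }
    cf <- ls_coef(X[sel, , drop = FALSE], r[sel])
    k <- length(cf)
    shift <- c(to_abs(cf[k - 1], cf[k]), 0)
    apply_shift(shift)

    r <- sqrt(P1[, 1]^2 + P1[, 2]^2)
    th <- unwrap_degrees(atan2(P1[, 2], P1[, 1]) * 180 / pi)
    th <- th - th[1]
    thr <- th * pi / 180
    zbase <- cbind(base, pmax(0, tt - 0.2), pmax(0, tt - 0.4), pmax(0, tt - 0.6), pmax(0, tt - 0.8))
    Z <- cbind(zbase, r * cos(thr), r * sin(thr))
    cf <- ls_coef(Z[sel, , drop = FALSE], P1[sel, 3])
    k <- length(cf)
    ab <- to_abs(cf[k - 1], cf[k])
    a_t <- ab[1]
    b_t <- ab[2]
    ang <- atan(sqrt(a_t^2 + b_t^2))
    if (ang > 1e-15) {
      # tilt slopes (a_t, b_t) define the plane normal (-a_t, -b_t, 1);
      # damp large corrections so the unwrap stays coherent while converging
      n <- c(-a_t, -b_t, 1)
      n <- n / sqrt(sum(n^2))
      applied <- min(ang, 0.1)
      axis <- c(n[2], -n[1], 0)
      s <- sqrt(sum(axis^2))
      if (s > 1e-15) {
        kv <- axis / s
        K <- matrix(c(0, kv[3], -kv[2], -kv[3], 0, kv[1], kv[2], -kv[1], 0), 3, 3)
        Rt <- diag(3) + sin(applied) * K + (1 - cos(applied)) * (K %*% K)
        apply_rot(t(Rt))
      }
    }
    if (ang < tol && sqrt(sum(shift^2)) < tol) break
  }

  th <- unwrap_degrees(atan2(P1[, 2], P1[, 1]) * 180 / pi)
  th <- th - th[1]
  apply_shift(c(0, 0, mean(P1[th <= 360, 3])))
  apply_rot(rotation_about_z(atan2(P1[1, 2], P1[1, 1])))

  th <- unwrap_degrees(atan2(P1[, 2], P1[, 1]) * 180 / pi)
  th <- th - th[1]
  new_aligned_cochlea(
    points = tibble::tibble(x = P1[, 1], y = P1[, 2], z = P1[, 3], theta = th),
    transform = list(rotation = t(A), translation = b),
    side = cloud_side(cloud)
  )
}

new_aligned_cochlea <- function(points, transform, side) {
  structure(
    list(points = points, transform = transform, side = side),
    class = "aligned_cochlea"
  )
}

#' Construct an already-canonical aligned cochlea
#'
#' Wraps points that are already expressed in the canonical modiolar frame
#' (z = modiolar axis, RW at angle 0) without re-estimating the frame.
#' Mostly useful for tests and for geometry that is generated canonically.
#'
#' @param points Data frame with x, y, z in the canonical frame, RW first.
#' @param side Ear side.
#' @return An `aligned_cochlea`.
#' @export
as_aligned_cochlea <- function(points, side = "right") {
  points <- tibble::as_tibble(points)[, c("x", "y", "z")]
  P <- as.matrix(points)
  raw <- as.numeric(atan2(P[, 2], P[, 1]) * 180 / pi)
  th <- unwrap_degrees(raw)
  th <- th - th[1]
  if (length(th) > 1L && th[length(th)] < 0) th <- -th
  new_aligned_cochlea(
    points = tibble::tibble(x = P[, 1], y = P[, 2], z = P[, 3], theta = th),
    transform = list(rotation = diag(3), translation = c(0, 0, 0)),
    side = side
  )
}

#' @export
print.aligned_cochlea <- function(x, ...) {
  cat(sprintf(
    "<aligned_cochlea> %d points, side = %s, theta span %.1f..%.1f deg\n",
    nrow(x$points), x$side, min(x$points$theta), max(x$points$theta)
  ))
  invisible(x)
}

#' Unwrapped angular positions along the lateral wall
#'
#' Returns the continuous (unwrapped) angle, in degrees, of each point of an
#' aligned cochlea in insertion order: 0 at the round window, increasing
#' toward the apex, exceeding 360 after one full turn.
#'
#' @param aligned An [align_cochlea()] result (or [as_aligned_cochlea()]).
#' @return Numeric vector of angles (degrees).
#' @export
unwrap_angles <- function(aligned) {
  stopifnot(inherits(aligned, "aligned_cochlea"))
  th <- aligned$points$theta
  if (length(th) > 1L) {
    net <- th[length(th)] - th[1]
    if (net == 0) {
      stop_cdl("angular trajectory has no net direction (self-crossing projection?)", "ordering")
    }
  }
  th
}

#' Apply a rigid transform to a point cloud
#'
#' @param cloud An `lw_cloud`.
#' @param rotation 3x3 rotation matrix (det +1).
#' @param translation Length-3 translation (mm).
#' @return A transformed `lw_cloud`.
#' @export
transform_cloud <- function(cloud, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(inherits(cloud, "lw_cloud"))
  if (abs(det(rotation) - 1) > 1e-9) {
    stop_cdl("`rotation` must be a proper rotation (det = +1)", "input")
  }
  P <- as.matrix(tibble::as_tibble(cloud)[, c("x", "y", "z")])
  Q <- sweep(P %*% t(rotation), 2, -translation)
  lateral_wall_cloud(
    tibble::tibble(x = Q[, 1], y = Q[, 2], z = Q[, 3]),
    side = cloud_side(cloud)
  )
}
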