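#' Electrode array geometry
#'
#' Positions of the contacts along the array, measured from the tip.
#' Contact 1 is the most apical. The default layout spaces 12 contacts
#' evenly with the first contact 1.0 mm behind the tip and ~2.4 mm pitch,
#' matching a 31.5-mm lateral-wall array.
#'
#' @param spec An [electrode_spec()].
#' @param contact_positions_mm Increasing distances from the tip (mm); must
#'   lie within the array length.
#' @return A list of class `electrode_array`.
#' @export
electrode_array <- function(spec = electrode_spec(),
                            contact_positions_mm = NULL) {
  if (is.null(contact_positions_mm)) {
    pitch <- (spec$length_mm - 5) / (spec$n_contacts - 1)
    contact_positions_mm <- 1.0 + pitch * (seq_len(spec$n_contacts) - 1)
  }
  if (length(contact_positions_mm) != spec$n_contacts) {
    stop_cdl("one position per contact required", "input")
  }
  if (is.unsorted(contact_positions_mm, strictly = TRUE)) {
    stop_cdl("contact positions must increase from tip to base", "input")
  }
  if (any(contact_positions_mm < 0) || any(contact_positions_mm > spec$length_mm)) {
    stop_cdl("contact positions must lie within the array", "input")
  }
  structure(
    list(spec = spec, contact_positions_mm = contact_positions_mm),
    class = "electrode_array"
  )
}

#' Simulate insertion of an electrode array
#'
#' Lays the array along the intracochlear trajectory obtained by offsetting
#' the lateral wall radially toward the modiolar axis by `wall_offset_mm`
#' (the array sits inside the scala, not on the wall). Insertion starts at
#' the round window (theta = 0); the tip advances along the trajectory until
#' the full array length is inserted or the trajectory ends. Each contact is
#' mapped to the unwrapped angle of its trajectory point.
#'
#' @param curve An angle-parameterised `lw_spline` in the canonical frame.
#' @param array An [electrode_array()].
#' @param wall_offset_mm Radial inset of the trajectory from the wall (mm).
#' @return An `insertion_result`: list with `contacts` (tibble contact,
#'   from_tip_mm, arc_mm, theta_deg), `ia_contact_span`, `ia_tip_from_rw`
#'   (degrees), `insertion_depth_mm`, `full_insertion`, `trajectory_length_mm`.
#' @export
simulate_insertion <- function(curve, array = electrode_array(), wall_offset_mm = 0.5) {
  stopifnot(inherits(curve, "lw_spline"))
  if (curve$param != "angle") {
    stop_cdl("insertion needs an angle-parameterised curve", "input")
  }
  if (wall_offset_mm < 0) stop_cdl("wall offset must be non-negative", "domain")

  # offset trajectory and its cumulative arc length, on a fine angular grid
  g <- seq(curve$theta_range[1], curve$theta_range[2], by = 0.05)
  pts <- eval_spline(curve, g)
  rad <- sqrt(pts$x^2 + pts$y^2)
  # the offset trajectory ends where the wall radius shrinks to the offset
  # (near the apex); insertion beyond that point is impossible
  infeasible <- which(rad <= wall_offset_mm + 1e-9)
  if (length(infeasible)) {
    if (infeasible[1] <= 2L) {
      stop_cdl("wall offset exceeds the local radius of the trajectory", "domain")
    }
    keep <- seq_len(infeasible[1] - 1L)
    g <- g[keep]
    pts <- pts[keep, ]
    rad <- rad[keep]
  }
  f <- (rad - wall_offset_mm) / rad
  M <- cbind(pts$x * f, pts$y * f, pts$z)
  s_cum <- c(0, cumsum(sqrt(rowSums(diff(M)^2))))
  total <- s_cum[length(s_cum)]
  theta_of_arc <- approxfun(s_cum, g)

  L <- array$spec$length_mm
  full <- total >= L
  depth <- min(L, total)
  tip_arc <- depth
  contact_arc <- pmax(0, tip_arc - array$contact_positions_mm)
  contacts <- tibble::tibble(
    contact = seq_along(contact_arc),
    from_tip_mm = array$contact_positions_mm,
    arc_mm = contact_arc,
    theta_deg = theta_of_arc(contact_arc)
  )
  structure(
    list(
      contacts = contacts,
      ia_contact_span = contacts$theta_deg[1] - contacts$theta_deg[nrow(contacts)],
      ia_tip_from_rw = theta_of_arc(tip_arc),
      insertion_depth_mm = depth,
      full_insertion = full,
      trajectory_length_mm = total,
      wall_offset_mm = wall_offset_mm,
      electrode = array$spec
    ),
    class = "insertion_result"
  )
}

#' @export
print.insertion_result <- function(x, ...) {
  cat(sprintf(
    "<insertion_result> %s, depth %.1f mm, IA %.1f deg (contact span), %.1f deg (tip)\n",
    if (x$full_insertion) "full insertion" else "PARTIAL insertion",
    x$insertion_depth_mm, x$ia_contact_span, x$ia_tip_from_rw
  ))
  invisible(x)
}

#' Insertion angle of an implanted array
#'
#' Two conventions are reported. `"contact_span"` (the radiographic
#' convention: angle between the most apical and most basal contacts) is the
#' default used with [cdl_reference_from_ia()]; `"tip_from_rw"` is the angle
#' of the most apical trajectory point from the round window. The tip extends
#' beyond contact 1, so contact_span <= tip_from_rw always.
#'
#' @param result A [simulate_insertion()] result.
#' @param convention `"contact_span"` or `"tip_from_rw"`.
#' @return Insertion angle in degrees.
#' @export
insertion_angle <- function(result, convention = c("contact_span", "tip_from_rw")) {
  stopifnot(inherits(result, "insertion_result"))
  convention <- match.arg(convention)
  if (any(!is.finite(result$contacts$theta_deg))) {
    stop_cdl("unmapped contacts in insertion result", "input")
  }
  switch(convention,
    contact_span = result$ia_contact_span,
    tip_from_rw = result$ia_tip_from_rw
  )
}
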