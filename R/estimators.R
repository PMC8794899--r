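#' CDL estimate records
#'
#' Every estimator in the package returns a `cdl_estimate`: a tibble with one
#' row per estimate carrying the value together with everything needed to
#' compare it fairly — the method, the angular extent theta it covers, the
#' reference surface (lateral wall vs organ of Corti) and the corrections
#' already applied. Keeping the surface and corrections on the record makes
#' it impossible to silently mix a 0.9-scaled organ-of-Corti length with a
#' lateral-wall length.
#'
#' @param cdl_mm Length in mm.
#' @param method One of `"spline3D"`, `"A_value"`, `"elliptic_SW"`, `"reference"`.
#' @param theta_deg Angular extent covered by the estimate (degrees).
#' @param surface `"lateral_wall"` or `"organ_of_corti"`.
#' @param corrections Character; `""` or `+`-separated tags from
#'   `oc_0.9`, `res_10_9`.
#' @param ... Extra identifying columns (e.g. `specimen_id`), recycled.
#' @return A tibble of class `cdl_estimate`.
#' @export
new_cdl_estimate <- function(cdl_mm, method, theta_deg, surface = "lateral_wall",
                             corrections = "", ...) {
  if (any(cdl_mm < 0)) stop_cdl("CDL must be non-negative", "domain")
  out <- tibble::tibble(
    cdl_mm = as.numeric(cdl_mm),
    method = method,
    theta_deg = theta_deg,
    surface = surface,
    corrections = corrections,
    ...
  )
  class(out) <- c("cdl_estimate", class(out))
  out
}

#' A-value (Escude) CDL formula
#'
#' Lateral-wall length of the cochlea up to insertion angle theta from the
#' basal-turn diameter A: `2.62 * A * ln(1 + theta/235)`. Theta is in
#' degrees — the constant 235 is degree-valued, and using radians silently
#' inflates the estimate.
#'
#' @param A Basal-turn diameter in mm (vectorised).
#' @param theta Angular extent in degrees (>= 0).
#' @param ... Extra identifying columns passed to [new_cdl_estimate()].
#' @return A `cdl_estimate` tibble.
#' @export
#' @examples
#' cdl_escude(9.0, 900)$cdl_mm # 37.13 mm
cdl_escude <- function(A, theta = 900, ...) {
  if (any(A <= 0)) stop_cdl("A-value must be positive", "domain")
  if (any(theta < 0)) stop_cdl("theta must be non-negative", "domain")
  new_cdl_estimate(
    cdl_mm = 2.62 * A * log(1 + theta / 235),
    method = "A_value", theta_deg = theta, surface = "lateral_wall", ...
  )
}

#' Full-cochlea A-value CDL
#'
#' The full-insertion special case of [cdl_escude()] with theta fixed at 900
#' degrees (2.5 turns, 100% coverage). In `mode = "exact"` the logarithm is
#' evaluated exactly and the result equals `cdl_escude(A, 900)`;
#' `mode = "printed_constant"` replaces `ln(1 + 900/235) = 1.5748...` by the
#' two-decimal constant 1.57 that circulates in the clinical literature
#' (a ~0.3% truncation).
#'
#' @param A Basal-turn diameter in mm.
#' @param mode `"exact"` or `"printed_constant"`.
#' @param theta_full Full-cochlea angle (degrees), 900 unless a sensitivity
#'   analysis overrides it.
#' @param ... Extra identifying columns.
#' @return A `cdl_estimate` tibble.
#' @export
cdl_escude_full <- function(A, mode = c("exact", "printed_constant"),
                            theta_full = 900, ...) {
  mode <- match.arg(mode)
  if (any(A <= 0)) stop_cdl("A-value must be positive", "domain")
  value <- if (mode == "exact") {
    2.62 * A * log(1 + theta_full / 235)
  } else {
    2.62 * A * 1.57
  }
  new_cdl_estimate(
    cdl_mm = value, method = "A_value", theta_deg = theta_full,
    surface = "lateral_wall", ...
  )
}

#' Default percentage-of-basal-turn-length profile
#'
#' Monotone scale factor pBTL(theta) converting the basal-turn bracket of the
#' elliptic-circular formula to a partial or full CDL, normalised so that
#' pBTL(360) = 1. The published profile behind the planning software is not
#' reprinted in the clinical sources, so the package default reuses the
#' Escude angular-length shape, `ln(1 + theta/235) / ln(1 + 360/235)` — an
#' approximation, flagged as such, and replaceable by any user profile.
#'
#' @param theta Angle in degrees.
#' @return Dimensionless positive scale factor.
#' @export
pbtl_escude <- function(theta) {
  log(1 + theta / 235) / log(1 + 360 / 235)
}
attr(pbtl_escude, "approximation") <- TRUE

#' Elliptic-circular (A/B-value) CDL formula
#'
#' The otosurgical planning software formula: the basal-turn lateral-wall
#' length is the elliptic-circular bracket
#' `1.18 (A - 0.7) + 2.69 (B - 0.7) - sqrt(0.72 (A - 0.7)(B - 0.7))`
#' and the CDL up to angle theta is the bracket scaled by pBTL(theta).
#'
#' @param A,B Basal-turn diameter and width in mm (must exceed 0.7, the
#'   formula's offsets). Vectorised.
#' @param theta Angular extent in degrees.
#' @param pbtl pBTL profile function; defaults to [pbtl_escude()].
#' @param ... Extra identifying columns.
#' @return A `cdl_estimate` tibble with method `"elliptic_SW"`.
#' @export
#' @examples
#' cdl_elliptic(9.0, 6.5, theta = 360)$cdl_mm # bracket itself: 19.509 mm
cdl_elliptic <- function(A, B, theta = 900, pbtl = pbtl_escude, ...) {
  if (any(A <= 0.7) || any(B <= 0.7)) {
    stop_cdl("A and B must exceed 0.7 mm (formula offsets)", "domain")
  }
  bracket <- 1.18 * (A - 0.7) + 2.69 * (B - 0.7) - sqrt(0.72 * (A - 0.7) * (B - 0.7))
  new_cdl_estimate(
    cdl_mm = pbtl(theta) * bracket,
    method = "elliptic_SW", theta_deg = theta, surface = "lateral_wall", ...
  )
}

has_correction <- function(est, tag) {
  vapply(
    strsplit(est$corrections, "+", fixed = TRUE),
    function(x) tag %in% x, logical(1)
  )
}

add_correction <- function(corrections, tag) {
  ifelse(corrections == "", tag, paste(corrections, tag, sep = "+"))
}

#' Convert a lateral-wall CDL to the organ of Corti
#'
#' The planning software reports CDL along the organ of Corti as 0.9 times
#' the lateral-wall length. The conversion is recorded on the estimate and
#' guarded against double application.
#'
#' @param est A `cdl_estimate` with surface `"lateral_wall"`.
#' @return The estimate scaled by 0.9 with surface `"organ_of_corti"`.
#' @export
to_organ_of_corti <- function(est) {
  stopifnot(inherits(est, "cdl_estimate"))
  if (any(est$surface != "lateral_wall") || any(has_correction(est, "oc_0.9"))) {
    stop_cdl("organ-of-Corti factor already applied", "double_correction")
  }
  est$cdl_mm <- est$cdl_mm * 0.9
  est$surface <- "organ_of_corti"
  est$corrections <- add_correction(est$corrections, "oc_0.9")
  est
}

#' Resolution (10/9) correction
#'
#' Clinical-resolution segmentations place lateral-wall points too close to
#' the modiolus; lengths measured from high-resolution micro-CT run about 10%
#' longer. This correction multiplies the CDL by 10/9 and records the fact.
#' Applying it on top of the 0.9 organ-of-Corti factor restores the original
#' value exactly (0.9 x 10/9 = 1).
#'
#' @param est A `cdl_estimate` without the correction applied.
#' @return The corrected estimate.
#' @export
apply_resolution_correction <- function(est) {
  stopifnot(inherits(est, "cdl_estimate"))
  if (any(has_correction(est, "res_10_9"))) {
    stop_cdl("resolution correction already applied", "double_correction")
  }
  est$cdl_mm <- est$cdl_mm * 10 / 9
  est$corrections <- add_correction(est$corrections, "res_10_9")
  est
}

#' Electrode array specification
#'
#' @param length_mm Physical array length in mm (default the 31.5 mm
#'   lateral-wall array used throughout the package).
#' @param n_contacts Number of contacts.
#' @param name Label.
#' @return A list of class `electrode_spec`.
#' @export
electrode_spec <- function(length_mm = 31.5, n_contacts = 12L, name = "31.5 mm lateral-wall array") {
  if (length_mm <= 0) stop_cdl("electrode length must be positive", "domain")
  if (n_contacts < 2L) stop_cdl("need at least 2 contacts", "domain")
  structure(
    list(length_mm = length_mm, n_contacts = as.integer(n_contacts), name = name),
    class = "electrode_spec"
  )
}

#' Cochlear coverage from a CDL
#'
#' CC(%) = electrode length / CDL x 100.
#'
#' @param cdl_mm CDL in mm (numeric or `cdl_estimate`).
#' @param electrode An [electrode_spec()].
#' @return Coverage in percent.
#' @export
predict_cc <- function(cdl_mm, electrode = electrode_spec()) {
  if (inherits(cdl_mm, "cdl_estimate")) cdl_mm <- cdl_mm$cdl_mm
  if (any(cdl_mm <= 0)) stop_cdl("CDL must be positive", "domain")
  electrode$length_mm / cdl_mm * 100
}

#' Insertion angle from cochlear coverage
#'
#' IA(deg) = CC(%) x 900 / 100: full coverage corresponds to the 900-degree
#' (2.5-turn) full cochlea.
#'
#' @param cc_percent Coverage in percent.
#' @param theta_full Full-cochlea angle, 900 degrees by default.
#' @return Insertion angle in degrees.
#' @export
predict_ia <- function(cc_percent, theta_full = 900) {
  if (any(cc_percent <= 0)) stop_cdl("coverage must be positive", "domain")
  cc_percent * theta_full / 100
}

#' Coverage and insertion-angle prediction
#'
#' @param cdl An estimate (numeric mm or `cdl_estimate` rows).
#' @param electrode An [electrode_spec()].
#' @param theta_full Full-cochlea angle (degrees).
#' @return Tibble with cc_percent and ia_deg (one row per estimate).
#' @export
predict_coverage <- function(cdl, electrode = electrode_spec(), theta_full = 900) {
  cc <- predict_cc(cdl, electrode)
  tibble::tibble(cc_percent = cc, ia_deg = predict_ia(cc, theta_full))
}

#' Reference CDL from a measured insertion angle
#'
#' Inverts the coverage relations for a fully inserted array of known length:
#' CDL = length x 900 / IA. This is the insertion-angle-based reference
#' against which the imaging estimators are benchmarked.
#'
#' @param ia Insertion angle in degrees (> 0).
#' @param electrode An [electrode_spec()].
#' @param theta_full Full-cochlea angle (degrees).
#' @param ... Extra identifying columns.
#' @return A `cdl_estimate` with method `"reference"`.
#' @export
cdl_reference_from_ia <- function(ia, electrode = electrode_spec(), theta_full = 900, ...) {
  if (any(ia <= 0)) stop_cdl("insertion angle must be positive", "domain")
  new_cdl_estimate(
    cdl_mm = electrode$length_mm * theta_full / ia,
    method = "reference", theta_deg = theta_full, surface = "lateral_wall", ...
  )
}
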