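#' Parametric spiral parameters
#'
#' The synthetic lateral wall is a decaying elliptic spiral:
#' radius `r(theta) = r0 (1 - decay * theta)`, with basal ellipticity
#' (y scaled by `1 - ellipticity`) blended out smoothly between 360 and 540
#' degrees, and a piecewise-linear axial rise that is twice as steep apically
#' (break at `pitch_break_deg`) totalling `height_mm` over the full extent.
#' The default preset is calibrated so a cohort reproduces the clinically
#' reported ranges: A around 9 mm, full lateral-wall CDL around 41 mm
#' (within 38-46 mm), height 4 mm over 2.5 turns.
#'
#' @param r0 Basal lateral-wall radius (mm).
#' @param decay Radial shrink per degree (dimensionless/deg).
#' @param ellipticity Basal-turn eccentricity (0 = circular).
#' @param height_mm Total axial rise base-to-apex (mm).
#' @param pitch_break_deg Angle at which the rise doubles its slope.
#' @param turns_deg Total angular extent (degrees, 720-990).
#' @return A list of class `spiral_params`.
#' @export
spiral_params <- function(r0 = 4.95, decay = 1.0e-3, ellipticity = 0.16,
                          height_mm = 4.0, pitch_break_deg = 540,
                          turns_deg = 900) {
  if (r0 <= 0) stop_cdl("r0 must be positive", "domain")
  if (turns_deg <= 0 || turns_deg > 990) {
    stop_cdl("turns_deg must lie in (0, 990]", "domain")
  }
  # anatomical cochleas cover 2 to 2.75 turns; shorter extents are allowed
  # for calibration geometry (circles, partial turns)
  if (1 - decay * turns_deg <= 0) {
    stop_cdl("radius must stay positive over the full extent", "generation")
  }
  structure(
    list(
      r0 = r0, decay = decay, ellipticity = ellipticity,
      height_mm = height_mm, pitch_break_deg = pitch_break_deg,
      turns_deg = turns_deg
    ),
    class = "spiral_params"
  )
}

spiral_point <- function(params, theta) {
  r <- params$r0 * (1 - params$decay * theta)
  e <- params$ellipticity
  # smoothstep blend of the basal ellipticity, gone by 540 degrees
  w <- ifelse(theta <= 360, 1,
    ifelse(theta >= 540, 0, {
      u <- (540 - theta) / 180
      u * u * (3 - 2 * u)
    })
  )
  th <- theta * pi / 180
  brk <- params$pitch_break_deg
  p1 <- params$height_mm / (brk + 2 * (params$turns_deg - brk))
  cbind(
    x = r * cos(th),
    y = r * (1 - e * w) * sin(th),
    z = ifelse(theta <= brk, p1 * theta, p1 * brk + 2 * p1 * (theta - brk))
  )
}

#' Generate a synthetic cochlear lateral wall with ground truth
#'
#' Evaluates the parametric spiral and computes its ground truth: the
#' cumulative lateral-wall length cdl_lw(theta) by dense polyline integration
#' (step 0.005 degrees; refining the step changes the full CDL by far less
#' than 1e-6 mm), the analytic A/B landmark chords, and the axial height.
#'
#' @param params A [spiral_params()].
#' @return A list of class `cochlear_spiral` with `params`, `curve(theta)`
#'   (matrix-valued function), and `truth`: list with `full_cdl_mm`,
#'   `cdl_lw(theta)` (function, mm), `A_mm`, `B_mm`, `H_mm`.
#' @export
make_spiral <- function(params = spiral_params()) {
  stopifnot(inherits(params, "spiral_params"))
  step <- 0.005
  gth <- seq(0, params$turns_deg, by = step)
  P <- spiral_point(params, gth)
  seg <- sqrt(rowSums(diff(P)^2))
  if (any(seg <= 0)) stop_cdl("self-intersecting spiral parameters", "generation")
  cum <- c(0, cumsum(seg))
  cdl_fun <- approxfun(gth, cum, rule = 2)

  chord_xy <- function(t1, t2) {
    p <- spiral_point(params, c(t1, t2))
    sqrt(sum((p[1, 1:2] - p[2, 1:2])^2))
  }
  truth <- list(
    full_cdl_mm = cum[length(cum)],
    cdl_lw = cdl_fun,
    A_mm = chord_xy(0, 180),
    B_mm = chord_xy(90, 270),
    H_mm = params$height_mm
  )
  structure(
    list(
      params = params,
      curve = function(theta) spiral_point(params, theta),
      truth = truth
    ),
    class = "cochlear_spiral"
  )
}

#' @export
print.cochlear_spiral <- function(x, ...) {
  cat(sprintf(
    "<cochlear_spiral> %.0f deg, CDL %.2f mm, A %.2f mm, B %.2f mm, H %.2f mm\n",
    x$params$turns_deg, x$truth$full_cdl_mm, x$truth$A_mm, x$truth$B_mm, x$truth$H_mm
  ))
  invisible(x)
}

#' Sample a point cloud from a synthetic spiral
#'
#' Uniform angular sampling plus isotropic Gaussian jitter; the round-window
#' point is the theta = 0 sample. Fully reproducible from the seed.
#'
#' @param spiral A [make_spiral()] result.
#' @param n Number of points (>= 4).
#' @param noise_sd Isotropic jitter SD (mm).
#' @param seed Integer seed.
#' @param side Ear side recorded on the cloud.
#' @return An [lateral_wall_cloud()].
#' @export
sample_point_cloud <- function(spiral, n = 500L, noise_sd = 0, seed = 1L,
                               side = "right") {
  stopifnot(inherits(spiral, "cochlear_spiral"))
  if (n < 4L) stop_cdl("need at least 4 points", "input")
  th <- seq(0, spiral$params$turns_deg, length.out = n)
  P <- spiral$curve(th)
  if (noise_sd > 0) {
    P <- P + withr::with_seed(seed, matrix(rnorm(3 * n, 0, noise_sd), ncol = 3))
  }
  lateral_wall_cloud(
    tibble::tibble(x = P[, 1], y = P[, 2], z = P[, 3]),
    side = side
  )
}

#' Per-method measurement error model
#'
#' Additive model for emulating the observed behaviour of the clinical
#' estimation methods: each method underestimates the reference by a fixed
#' bias and carries Gaussian measurement noise; raters add independent
#' jitter. Default biases are the reference-minus-method differences
#' reported for the six imaging/method combinations (mm), default noise SDs
#' their reported spreads.
#'
#' @param methods Method labels.
#' @param bias_mm Reference - method bias per method (mm; positive =
#'   underestimation).
#' @param noise_sd_mm Per-method measurement noise SD (mm).
#' @param rater_sd_mm Additional per-rater jitter SD (mm).
#' @param reference_sd_mm Measurement noise of the reference itself (mm).
#' @return A list of class `cdl_error_model`.
#' @export
measurement_error_model <- function(
    methods = c("3D-HRCT", "3D-CBCT", "A-HRCT", "A-CBCT", "SW-HRCT", "SW-CBCT"),
    bias_mm = c(7.7, 6.1, 7.2, 5.0, 6.1, 5.5),
    noise_sd_mm = c(1.4, 1.3, 1.2, 2.0, 1.8, 1.7),
    rater_sd_mm = 0.5,
    reference_sd_mm = 2.0) {
  if (length(bias_mm) != length(methods) || length(noise_sd_mm) != length(methods)) {
    stop_cdl("bias and noise must match the method list", "input")
  }
  if (any(noise_sd_mm < 0) || rater_sd_mm < 0 || reference_sd_mm < 0) {
    stop_cdl("standard deviations must be non-negative", "input")
  }
  structure(
    list(
      methods = methods, bias_mm = setNames(bias_mm, methods),
      noise_sd_mm = setNames(noise_sd_mm, methods),
      rater_sd_mm = rater_sd_mm, reference_sd_mm = reference_sd_mm
    ),
    class = "cdl_error_model"
  )
}

#' Simulate a measurement table from ground truth
#'
#' Observation = truth - bias + method noise + rater jitter, per
#' method x rater, plus reference rows (truth + reference noise, no bias).
#'
#' @param truth_cdl_mm True CDL per specimen (vector; names or seq used as ids).
#' @param model A [measurement_error_model()].
#' @param raters Number of raters (>= 1).
#' @param seed Integer seed.
#' @return Long tibble: specimen_id, method, rater_id, cdl_mm.
#' @export
simulate_measurements <- function(truth_cdl_mm, model = measurement_error_model(),
                                  raters = 2L, seed = 1L) {
  if (raters < 1L) stop_cdl("need at least one rater", "input")
  ids <- names(truth_cdl_mm) %||% sprintf("TB%02d", seq_along(truth_cdl_mm))
  grid <- tidyr::expand_grid(
    specimen_id = ids,
    method = c(model$methods, "reference"),
    rater_id = sprintf("R%d", seq_len(raters))
  )
  truth <- setNames(as.numeric(truth_cdl_mm), ids)
  withr::with_seed(seed, {
    bias <- ifelse(grid$method == "reference", 0, model$bias_mm[grid$method])
    msd <- ifelse(grid$method == "reference", model$reference_sd_mm,
      model$noise_sd_mm[grid$method]
    )
    # method noise is a specimen x method effect (both raters read the same
    # scan), rater jitter is independent per reading
    cell <- paste(grid$specimen_id, grid$method)
    ucell <- unique(cell)
    cell_sd <- msd[match(ucell, cell)]
    cell_noise <- setNames(rnorm(length(ucell), 0, cell_sd), ucell)
    rjit <- rnorm(nrow(grid), 0, model$rater_sd_mm)
    dplyr::mutate(
      grid,
      cdl_mm = as.numeric(truth[.data$specimen_id] - bias + cell_noise[cell] + rjit)
    )
  })
}

#' Generate a reproducible synthetic cohort
#'
#' Draws specimen-level spiral parameters around the default preset,
#' builds each spiral with its ground truth, samples lateral-wall clouds,
#' and simulates the per-method measurement table. This is the data supply
#' for the end-to-end comparisons.
#'
#' @param n_specimens Cohort size (>= 2; default 20).
#' @param base_params Preset around which specimens vary.
#' @param error_model A [measurement_error_model()].
#' @param raters Number of raters.
#' @param n_points,noise_sd Point-cloud sampling settings per specimen.
#' @param seed Integer master seed.
#' @param include_clouds Set `FALSE` to skip cloud sampling (faster).
#' @return A list of class `cdl_cohort`: `truths` (tibble specimen_id, A_mm,
#'   B_mm, H_mm, full_cdl_mm), `measurements` (long tibble), `spirals`,
#'   `clouds` (lists, by specimen), `seed`.
#' @export
generate_cohort <- function(n_specimens = 20L,
                            base_params = spiral_params(),
                            error_model = measurement_error_model(),
                            raters = 2L,
                            n_points = 500L, noise_sd = 0.1,
                            seed = 20L,
                            include_clouds = TRUE) {
  if (n_specimens < 2L) stop_cdl("cohort needs at least 2 specimens", "input")
  ids <- sprintf("TB%02d", seq_len(n_specimens))
  draws <- withr::with_seed(child_seed(seed, 0L), tibble::tibble(
    r0 = rnorm(n_specimens, base_params$r0, 0.22),
    ellipticity = pmax(0, rnorm(n_specimens, base_params$ellipticity, 0.03)),
    height_mm = rnorm(n_specimens, base_params$height_mm, 0.25)
  ))
  spirals <- purrr::pmap(draws, function(r0, ellipticity, height_mm) {
    make_spiral(spiral_params(
      r0 = r0, decay = base_params$decay, ellipticity = ellipticity,
      height_mm = height_mm, pitch_break_deg = base_params$pitch_break_deg,
      turns_deg = base_params$turns_deg
    ))
  })
  names(spirals) <- ids
  truths <- dplyr::bind_rows(purrr::imap(spirals, function(sp, id) {
    tibble::tibble(
      specimen_id = id,
      A_mm = sp$truth$A_mm, B_mm = sp$truth$B_mm, H_mm = sp$truth$H_mm,
      full_cdl_mm = sp$truth$full_cdl_mm
    )
  }))
  clouds <- NULL
  if (include_clouds) {
    clouds <- purrr::imap(spirals, function(sp, id) {
      sample_point_cloud(sp,
        n = n_points, noise_sd = noise_sd,
        seed = child_seed(seed, match(id, ids))
      )
    })
  }
  measurements <- simulate_measurements(
    setNames(truths$full_cdl_mm, ids),
    model = error_model, raters = raters,
    seed = child_seed(seed, 999L)
  )
  structure(
    list(
      truths = truths, measurements = measurements,
      spirals = spirals, clouds = clouds, seed = seed
    ),
    class = "cdl_cohort"
  )
}

#' @export
print.cdl_cohort <- function(x, ...) {
  cat(sprintf(
    "<cdl_cohort> %d specimens, CDL %.1f-%.1f mm, %d measurement rows\n",
    nrow(x$truths), min(x$truths$full_cdl_mm), max(x$truths$full_cdl_mm),
    nrow(x$measurements)
  ))
  invisible(x)
}
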