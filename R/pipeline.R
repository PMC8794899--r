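#' Run configuration
#'
#' Validated configuration for an end-to-end run. Unknown fields are
#' rejected so typos fail loudly.
#'
#' @param seed Integer master seed.
#' @param n_specimens Cohort size.
#' @param electrode_length_mm,n_contacts Electrode geometry.
#' @param theta_full Full-cochlea angle (degrees).
#' @param threshold_lo,threshold_hi Segmentation window.
#' @param voxel_spacing Phantom voxel spacing (mm).
#' @param wall_offset_mm Insertion trajectory inset (mm).
#' @param escude_mode `"exact"` or `"printed_constant"`.
#' @param apply_10_9 Apply the resolution correction to the formula-based
#'   estimates before comparison.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_specimens = 20L,
                       electrode_length_mm = 31.5, n_contacts = 12L,
                       theta_full = 900,
                       threshold_lo = -1024, threshold_hi = 280,
                       voxel_spacing = 0.2,
                       wall_offset_mm = 0.5,
                       escude_mode = "exact",
                       apply_10_9 = FALSE) {
  cfg <- list(
    seed = as.integer(seed), n_specimens = as.integer(n_specimens),
    electrode_length_mm = electrode_length_mm, n_contacts = as.integer(n_contacts),
    theta_full = theta_full,
    threshold_lo = threshold_lo, threshold_hi = threshold_hi,
    voxel_spacing = voxel_spacing,
    wall_offset_mm = wall_offset_mm,
    escude_mode = match.arg(escude_mode, c("exact", "printed_constant")),
    apply_10_9 = isTRUE(apply_10_9)
  )
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  if (cfg$n_specimens < 2L) stop_cdl("n_specimens must be >= 2", "config")
  if (cfg$electrode_length_mm <= 0) stop_cdl("electrode_length_mm must be > 0", "config")
  if (cfg$theta_full <= 0) stop_cdl("theta_full must be > 0", "config")
  if (cfg$threshold_lo >= cfg$threshold_hi) stop_cdl("threshold window is empty", "config")
  if (cfg$voxel_spacing < 0.05 || cfg$voxel_spacing > 0.5) {
    stop_cdl("voxel_spacing must be in [0.05, 0.5]", "config")
  }
  if (cfg$wall_offset_mm < 0) stop_cdl("wall_offset_mm must be >= 0", "config")
  invisible(cfg)
}

#' Read / write a run configuration as JSON
#'
#' Unknown keys in the file are rejected.
#'
#' @param path JSON file path.
#' @param config A `run_config` (write).
#' @return A `run_config` (read); `path` invisibly (write).
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    stop_cdl(paste("unknown config fields:", paste(extra, collapse = ", ")), "config")
  }
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Formula-based CDL estimates from a landmark table
#'
#' One estimate row per input row and method: the A-value estimate wherever
#' A is present, the elliptic-circular estimate wherever both A and B are.
#'
#' @param metrics Tibble with columns A_mm and optionally B_mm, plus any
#'   identifying columns (specimen_id, modality, rater_id) to carry through.
#' @param theta_full Full-cochlea angle.
#' @param escude_mode Passed to [cdl_escude_full()].
#' @param organ_of_corti Also emit 0.9-scaled organ-of-Corti rows for the
#'   elliptic method.
#' @return A `cdl_estimate` tibble.
#' @export
estimate_cdl <- function(metrics, theta_full = 900, escude_mode = "exact",
                         organ_of_corti = FALSE) {
  if (!"A_mm" %in% names(metrics)) stop_cdl("metrics need at least A_mm", "input")
  carry <- intersect(c("specimen_id", "modality", "rater_id"), names(metrics))
  warn_odd_metrics(metrics)
  out <- list()
  ok_a <- is.finite(metrics$A_mm)
  if (any(ok_a)) {
    args <- c(
      list(A = metrics$A_mm[ok_a], mode = escude_mode, theta_full = theta_full),
      as.list(metrics[ok_a, carry, drop = FALSE])
    )
    out$a_value <- do.call(cdl_escude_full, args)
  }
  if ("B_mm" %in% names(metrics)) {
    ok_b <- ok_a & is.finite(metrics$B_mm)
    if (any(ok_b)) {
      args <- c(
        list(A = metrics$A_mm[ok_b], B = metrics$B_mm[ok_b], theta = theta_full),
        as.list(metrics[ok_b, carry, drop = FALSE])
      )
      sw <- do.call(cdl_elliptic, args)
      out$elliptic <- if (organ_of_corti) to_organ_of_corti(sw) else sw
    }
  }
  dplyr::bind_rows(out)
}

warn_odd_metrics <- function(metrics) {
  if (all(c("A_mm", "B_mm") %in% names(metrics))) {
    bad <- is.finite(metrics$A_mm) & is.finite(metrics$B_mm) & metrics$A_mm < metrics$B_mm
    if (any(bad)) warn(sprintf("%d rows have A < B (unusual basal turn)", sum(bad)))
  }
  if (any(metrics$A_mm <= 5 | metrics$A_mm >= 13, na.rm = TRUE)) {
    warn("A-values outside the 5-13 mm sanity window")
  }
  invisible(metrics)
}

#' Read / write measurement tables
#'
#' CSV with a header; lengths in mm, angles in degrees.
#'
#' @param path CSV path.
#' @param table Tibble to write.
#' @return Tibble (read); `path` invisibly (write).
#' @export
read_measurement_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, comment = "#")
}

#' @rdname read_measurement_table
#' @export
write_measurement_table <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

#' End-to-end synthetic comparison pipeline
#'
#' Simulate a cohort, measure every specimen with the three estimator
#' families, simulate the electrode insertion for the reference, run the
#' comparison statistics and build the report. Writes all artifacts and a
#' manifest with config hash and per-file checksums when `outdir` is given.
#'
#' Stages: (1) cohort generation (spirals + ground truth + jittered clouds);
#' (2) geometric measurement per specimen: align, fit spline, 3D CDL and
#' A/B/H landmarks; (3) formula estimates from the measured landmarks;
#' (4) insertion simulation on the true wall and reference CDL from the
#' simulated insertion angle; (5) per-method summary, ANOVA + Dunnett vs the
#' simulated-measurement reference, correlations and two-rater ICC.
#'
#' @param config A [run_config()].
#' @param outdir Optional output directory.
#' @return List of class `cdl_pipeline_result`: `cohort`, `geometry`
#'   (per-specimen tibble), `estimates`, `insertions`, `report`, `manifest`.
#' @export
run_cdl_pipeline <- function(config = run_config(), outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  electrode <- electrode_spec(config$electrode_length_mm, config$n_contacts)
  cohort <- generate_cohort(
    n_specimens = config$n_specimens,
    seed = config$seed
  )

  geometry <- purrr::imap_dfr(cohort$clouds, function(cloud, id) {
    aligned <- align_cochlea(cloud)
    curve <- fit_lateral_wall_spline(aligned, smoothing = "gcv")
    metrics <- measure_basal_metrics(curve)
    tibble::tibble(
      specimen_id = id,
      cdl_3d_mm = arc_length(curve),
      A_mm = metrics$A_mm, B_mm = metrics$B_mm, H_mm = metrics$H_mm
    )
  })

  estimates <- estimate_cdl(
    geometry,
    theta_full = config$theta_full,
    escude_mode = config$escude_mode
  )
  if (config$apply_10_9) estimates <- apply_resolution_correction(estimates)

  insertions <- purrr::imap(cohort$spirals, function(sp, id) {
    th <- seq(0, sp$params$turns_deg, length.out = 800L)
    P <- sp$curve(th)
    aligned <- as_aligned_cochlea(tibble::tibble(x = P[, 1], y = P[, 2], z = P[, 3]))
    curve <- fit_lateral_wall_spline(aligned, smoothing = "none")
    simulate_insertion(curve, electrode_array(electrode), config$wall_offset_mm)
  })
  reference <- purrr::imap_dfr(insertions, function(ins, id) {
    ia <- insertion_angle(ins, "contact_span")
    dplyr::bind_cols(
      tibble::tibble(specimen_id = id, ia_deg = ia),
      cdl_reference_from_ia(ia, electrode, config$theta_full)[, "cdl_mm"]
    )
  })

  table <- cohort$measurements
  summary <- summarize_methods(table, electrode, config$theta_full)
  anova <- anova_methods(table |>
    dplyr::group_by(.data$method, .data$specimen_id) |>
    dplyr::summarise(cdl_mm = mean(.data$cdl_mm), .groups = "drop"))
  dunnett <- dunnett_vs_control(table |>
    dplyr::group_by(.data$method, .data$specimen_id) |>
    dplyr::summarise(cdl_mm = mean(.data$cdl_mm), .groups = "drop"))
  correlations <- correlate_with_reference(table)
  reliability <- reliability_by_method(table)
  report <- build_report(summary, anova, dunnett, correlations, reliability)

  manifest <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_run_config(config, file.path(outdir, "config.json"))
    write_measurement_table(table, file.path(outdir, "measurements.csv"))
    write_measurement_table(geometry, file.path(outdir, "geometry.csv"))
    write_measurement_table(estimates, file.path(outdir, "estimates.csv"))
    write_measurement_table(reference, file.path(outdir, "reference.csv"))
    write_report(report, outdir)
    files <- c(
      "config.json", "measurements.csv", "geometry.csv",
      "estimates.csv", "reference.csv", "report.json", "report.md"
    )
    manifest <- list(
      package_version = as.character(utils::packageVersion("cdlkit")),
      seed = config$seed,
      config_hash = unname(tools::md5sum(file.path(outdir, "config.json"))),
      checksums = as.list(tools::md5sum(file.path(outdir, files)))
    )
    jsonlite::write_json(
      manifest, file.path(outdir, "manifest.json"),
      auto_unbox = TRUE, pretty = TRUE
    )
  }

  structure(
    list(
      cohort = cohort, geometry = geometry, estimates = estimates,
      insertions = insertions, reference = reference,
      report = report, manifest = manifest, config = config
    ),
    class = "cdl_pipeline_result"
  )
}

#' @export
print.cdl_pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<cdl_pipeline_result> %d specimens (seed %d)\n",
    x$config$n_specimens, x$config$seed
  ))
  print(x$report$summary)
  invisible(x)
}

#' Simulate a cohort and write its files
#'
#' Thin file-writing wrapper over [generate_cohort()]: writes the
#' measurement table, ground truths, per-specimen clouds (CSV) and a
#' manifest. Re-running with the same seed reproduces identical files.
#'
#' @param outdir Output directory.
#' @param n_specimens Cohort size (>= 2).
#' @param seed Master seed.
#' @return The manifest list, invisibly.
#' @export
simulate_cohort_files <- function(outdir, n_specimens = 20L, seed = 20L) {
  cohort <- generate_cohort(n_specimens = n_specimens, seed = seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_measurement_table(cohort$measurements, file.path(outdir, "measurements.csv"))
  write_measurement_table(cohort$truths, file.path(outdir, "truths.csv"))
  cloud_files <- purrr::imap_chr(cohort$clouds, function(cl, id) {
    f <- file.path(outdir, sprintf("cloud_%s.csv", id))
    write_point_cloud(cl, f)
    f
  })
  files <- c(
    file.path(outdir, c("measurements.csv", "truths.csv")),
    unname(cloud_files)
  )
  manifest <- list(
    seed = as.integer(seed), n_specimens = as.integer(n_specimens),
    checksums = as.list(tools::md5sum(files))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(manifest)
}
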