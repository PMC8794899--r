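#' Lateral-wall point cloud
#'
#' Bundles the 3D points digitised on the cochlear lateral wall with the
#' round-window (RW) marker and the ear side. The RW point is the angular
#' zero reference for every downstream measurement; `side` records the
#' winding handedness (a left cochlea is the mirror image of a right one).
#'
#' @param points A data frame with numeric columns `x`, `y`, `z` (mm).
#' @param rw_index Row index of the round-window point (default first row).
#' @param side `"right"` or `"left"`.
#' @return An object of class `lw_cloud`: a tibble of points with attributes
#'   `rw_index` and `side`. The RW point is moved to the first row.
#' @export
#' @examples
#' th <- seq(0, 2 * pi, length.out = 50)
#' lateral_wall_cloud(data.frame(x = cos(th), y = sin(th), z = 0))
lateral_wall_cloud <- function(points, rw_index = 1L, side = c("right", "left")) {
  side <- match.arg(side)
  points <- tibble::as_tibble(points)
  if (!all(c("x", "y", "z") %in% names(points))) {
    stop_cdl("`points` must have columns x, y, z", "input")
  }
  points <- dplyr::select(points, "x", "y", "z")
  m <- as.matrix(points)
  if (!all(is.finite(m))) stop_cdl("point coordinates must be finite", "input")
  if (nrow(points) < 1L) stop_cdl("need at least one point", "input")
  if (rw_index < 1L || rw_index > nrow(points)) {
    stop_cdl("`rw_index` out of range", "input")
  }
  if (nrow(points) >= 2L) {
    # duplicate guard: consecutive points closer than 1e-9 mm are degenerate
    steps <- sqrt(rowSums(diff(m)^2))
    if (any(steps < 1e-9)) {
      stop_cdl("duplicate points (within 1e-9 mm) in cloud", "input")
    }
  }
  if (rw_index != 1L) {
    points <- points[c(rw_index, setdiff(seq_len(nrow(points)), rw_index)), ]
  }
  structure(points, class = c("lw_cloud", class(points)), side = side)
}

#' @export
print.lw_cloud <- function(x, ...) {
  cat(sprintf(
    "<lw_cloud> %d points, side = %s, RW at row 1\n",
    nrow(x), attr(x, "side")
  ))
  NextMethod()
}

cloud_side <- function(cloud) attr(cloud, "side") %||% "right"

#' Read a lateral-wall point cloud
#'
#' Reads `x,y,z` point clouds (mm) from CSV/XYZ tables or ASCII PLY files.
#' For CSV/XYZ the round-window point is taken as the first row unless a
#' sidecar JSON (`<file>.json` with fields `rw_index` and optionally `side`)
#' is present.
#'
#' @param path File path; format chosen by extension (`.ply` vs anything else).
#' @param side Ear side, overridden by the sidecar if present.
#' @return An [lateral_wall_cloud()] object.
#' @export
read_point_cloud <- function(path, side = "right") {
  rw_index <- 1L
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    rw_index <- as.integer(meta$rw_index %||% 1L)
    side <- meta$side %||% side
  }
  if (grepl("\\.ply$", path, ignore.case = TRUE)) {
    pts <- read_ply_ascii(path)
  } else {
    pts <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
    names(pts) <- tolower(names(pts))
  }
  lateral_wall_cloud(pts, rw_index = rw_index, side = side)
}

#' Write a lateral-wall point cloud
#'
#' @param cloud An `lw_cloud`.
#' @param path Output path; `.ply` writes ASCII PLY (with a sidecar JSON for
#'   the RW index and side), anything else a CSV with the RW point first.
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(cloud, path) {
  if (grepl("\\.ply$", path, ignore.case = TRUE)) {
    write_ply_ascii(cloud, path)
    jsonlite::write_json(
      list(rw_index = 1L, side = cloud_side(cloud)),
      paste0(path, ".json"),
      auto_unbox = TRUE
    )
  } else {
    readr::write_csv(tibble::as_tibble(cloud), path)
  }
  invisible(path)
}

# Minimal ASCII PLY reader (vertex element with x/y/z properties only).
read_ply_ascii <- function(path) {
  lines <- readLines(path)
  if (!identical(lines[1], "ply")) stop_cdl("not a PLY file", "io")
  if (!any(grepl("^format ascii", lines))) {
    stop_cdl("only ASCII PLY is supported", "io")
  }
  hdr_end <- match("end_header", lines)
  vline <- grep("^element vertex", lines[seq_len(hdr_end)], value = TRUE)
  if (length(vline) != 1L) stop_cdl("PLY must declare one vertex element", "io")
  n <- as.integer(strsplit(vline, "\\s+")[[1]][3])
  props <- sub("^property \\S+ ", "", grep("^property ", lines[seq_len(hdr_end)], value = TRUE))
  body <- lines[(hdr_end + 1L):(hdr_end + n)]
  vals <- matrix(
    as.numeric(unlist(strsplit(trimws(body), "\\s+"))),
    nrow = n, byrow = TRUE
  )
  colnames(vals) <- props[seq_len(ncol(vals))]
  tibble::as_tibble(vals[, c("x", "y", "z"), drop = FALSE])
}

write_ply_ascii <- function(cloud, path) {
  m <- as.matrix(tibble::as_tibble(cloud)[, c("x", "y", "z")])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0",
    sprintf("element vertex %d", nrow(m)),
    "property double x", "property double y", "property double z",
    "end_header"
  ), con)
  writeLines(apply(format(m, digits = 17, trim = TRUE, scientific = FALSE), 1, paste, collapse = " "), con)
  invisible(path)
}
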