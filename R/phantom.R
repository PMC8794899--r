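#' Default lumen radius profile
#'
#' Radius of the fluid lumen (mm) as a function of the unwrapped angle:
#' wide basally, tapering apically like the scala.
#'
#' @param theta Angle in degrees.
#' @return Lumen radius in mm.
#' @export
lumen_radius_default <- function(theta) {
  0.6 - 0.3 * pmin(theta, 780) / 780
}

#' Rasterize a tube around a centerline into a CT-like voxel phantom
#'
#' Voxels whose centers lie within the (angle-dependent) lumen radius of the
#' centerline get the fluid intensity; a surrounding bone shell of fixed
#' thickness gets the bone intensity; everything else is air background.
#' Intensities default to an HU-like HRCT preset (fluid 0, bone +700, air
#' -1000); a CBCT-like preset uses shifted gray values with its own window.
#'
#' @param centerline Matrix/data frame of centerline samples (columns x, y, z,
#'   mm), finely spaced (the tube is the union of balls around the samples).
#' @param lumen_radius Lumen radius per sample: a function of the sample
#'   index-matched `theta` argument, or a vector (recycled).
#' @param theta Unwrapped angle per sample (degrees), used only to evaluate
#'   a functional `lumen_radius`.
#' @param spacing Voxel spacing in mm (0.05-0.5).
#' @param shell_mm Bone shell thickness (mm). Keep >= 3 voxels so the shell
#'   is voxel-watertight; a leaky shell connects lumen and background.
#' @param preset `"HRCT"` (HU-like) or `"CBCT"` (gray values: fluid 1000,
#'   bone 1700, background 24).
#' @param max_voxels Guard against accidental huge grids.
#' @return A list of class `voxel_phantom`: `vol` (integer 3D array),
#'   `xs`, `ys`, `zs` voxel-center coordinates, `spacing`, `preset`,
#'   `window` (the segmentation window for the preset).
#' @export
rasterize_to_volume <- function(centerline, lumen_radius = lumen_radius_default,
                                theta = NULL, spacing = 0.2, shell_mm = 0.6,
                                preset = c("HRCT", "CBCT"),
                                max_voxels = 5e7) {
  preset <- match.arg(preset)
  if (spacing < 0.05 || spacing > 0.5) {
    stop_cdl("spacing must be in [0.05, 0.5] mm", "domain")
  }
  C <- as.matrix(as.data.frame(centerline))[, 1:3, drop = FALSE]
  if (nrow(C) == 0L) stop_cdl("empty centerline", "input")
  lr <- if (is.function(lumen_radius)) {
    if (is.null(theta)) stop_cdl("functional lumen_radius needs `theta`", "input")
    lumen_radius(theta)
  } else {
    rep_len(lumen_radius, nrow(C))
  }
  if (any(lr <= 0)) stop_cdl("lumen radius must be positive", "domain")

  pad <- max(lr) + shell_mm + 2 * spacing
  xs <- seq(min(C[, 1]) - pad, max(C[, 1]) + pad, by = spacing)
  ys <- seq(min(C[, 2]) - pad, max(C[, 2]) + pad, by = spacing)
  zs <- seq(min(C[, 3]) - pad, max(C[, 3]) + pad, by = spacing)
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  if (as.double(nx) * ny * nz > max_voxels) {
    stop_cdl("voxel grid too large; increase `spacing` or `max_voxels`", "memory")
  }

  dist <- array(Inf, c(nx, ny, nz))
  rnear <- array(0, c(nx, ny, nz))
  rmax <- max(lr) + shell_mm
  for (i in seq_len(nrow(C))) {
    p <- C[i, ]
    ix <- which(abs(xs - p[1]) <= rmax)
    iy <- which(abs(ys - p[2]) <= rmax)
    iz <- which(abs(zs - p[3]) <= rmax)
    if (!length(ix) || !length(iy) || !length(iz)) next
    d <- sqrt(outer(outer((xs[ix] - p[1])^2, (ys[iy] - p[2])^2, "+"), (zs[iz] - p[3])^2, "+"))
    sub <- dist[ix, iy, iz]
    upd <- d < sub
    sub[upd] <- d[upd]
    dist[ix, iy, iz] <- sub
    rs <- rnear[ix, iy, iz]
    rs[upd] <- lr[i]
    rnear[ix, iy, iz] <- rs
  }

  iv <- phantom_intensities(preset)
  vol <- array(iv$background, c(nx, ny, nz))
  vol[dist <= rnear + shell_mm] <- iv$bone
  vol[dist <= rnear] <- iv$fluid
  structure(
    list(
      vol = vol, xs = xs, ys = ys, zs = zs, spacing = spacing,
      preset = preset, window = iv$window
    ),
    class = "voxel_phantom"
  )
}

phantom_intensities <- function(preset) {
  if (preset == "HRCT") {
    # HU-like: the clinical segmentation window is -1024..+280 HU
    list(fluid = 0L, bone = 700L, background = -1000L, window = c(-1024, 280))
  } else {
    # CBCT gray values are not HU; a shifted synthetic window stands in
    list(fluid = 1000L, bone = 1700L, background = 24L, window = c(30, 1400))
  }
}

#' @export
print.voxel_phantom <- function(x, ...) {
  cat(sprintf(
    "<voxel_phantom> %dx%dx%d voxels at %.2f mm (%s preset)\n",
    dim(x$vol)[1], dim(x$vol)[2], dim(x$vol)[3], x$spacing, x$preset
  ))
  invisible(x)
}

#' Threshold segmentation of a voxel phantom
#'
#' Selects voxels with intensity in `[lo, hi]` (default the HRCT window
#' -1024..+280). Because air background also falls inside a CT fluid window,
#' a `seed_point` (mm coordinates inside the lumen) restricts the mask to
#' its 6-connected component — the voxel analogue of seeding a region-growing
#' segmentation in the cochlear fluid. Boundary voxels (mask voxels with at
#' least one non-mask 6-neighbour) are returned as points at voxel centers.
#'
#' @param phantom A [rasterize_to_volume()] result.
#' @param lo,hi Intensity window; defaults to the phantom preset's window.
#' @param seed_point Optional length-3 point (mm) inside the structure.
#' @return Tibble of boundary points (x, y, z, mm).
#' @export
threshold_segment <- function(phantom, lo = NULL, hi = NULL, seed_point = NULL) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  lo <- lo %||% phantom$window[1]
  hi <- hi %||% phantom$window[2]
  if (lo >= hi) stop_cdl("need lo < hi", "input")
  m <- phantom$vol >= lo & phantom$vol <= hi
  if (!any(m)) stop_cdl("empty mask: window selects no voxels", "segmentation")
  if (!is.null(seed_point)) {
    m <- mask_component(phantom, m, seed_point)
  }
  bnd <- mask_boundary(m)
  w <- which(bnd)
  a <- arrayInd(w, dim(m))
  tibble::tibble(
    x = phantom$xs[a[, 1]], y = phantom$ys[a[, 2]], z = phantom$zs[a[, 3]]
  )
}

# 6-connected component of the mask containing the seed (igraph components).
mask_component <- function(phantom, m, seed_point) {
  dims <- dim(m)
  si <- c(
    which.min(abs(phantom$xs - seed_point[1])),
    which.min(abs(phantom$ys - seed_point[2])),
    which.min(abs(phantom$zs - seed_point[3]))
  )
  seed_lin <- si[1] + (si[2] - 1L) * dims[1] + (si[3] - 1L) * dims[1] * dims[2]
  if (!m[seed_lin]) stop_cdl("seed point is not inside the mask", "segmentation")
  idx <- which(m)
  pos <- integer(prod(dims))
  pos[idx] <- seq_along(idx)
  ar <- arrayInd(idx, dims)
  edges <- integer(0)
  for (d in 1:3) {
    nb <- ar
    nb[, d] <- nb[, d] + 1L
    ok <- nb[, d] <= dims[d]
    nlin <- nb[ok, 1] + (nb[ok, 2] - 1L) * dims[1] + (nb[ok, 3] - 1L) * dims[1] * dims[2]
    both <- m[nlin]
    edges <- c(edges, rbind(pos[idx[ok][both]], pos[nlin[both]]))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  keep <- comp == comp[pos[seed_lin]]
  m2 <- array(FALSE, dims)
  m2[idx[keep]] <- TRUE
  m2
}

mask_boundary <- function(m) {
  dims <- dim(m)
  shift <- function(a, d, by) {
    out <- array(FALSE, dims)
    src <- dst <- lapply(dims, seq_len)
    if (by == 1L) {
      src[[d]] <- 1:(dims[d] - 1L); dst[[d]] <- 2:dims[d]
    } else {
      src[[d]] <- 2:dims[d]; dst[[d]] <- 1:(dims[d] - 1L)
    }
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
  }
  bnd <- array(FALSE, dims)
  for (d in 1:3) {
    for (by in c(1L, -1L)) {
      bnd <- bnd | (m & !shift(m, d, by))
    }
  }
  bnd
}

#' Build a CT-like phantom of a synthetic cochlea
#'
#' The generator curve is the lateral wall, so the fluid tube is centred on
#' the curve inset medially (toward the axis) by the lumen radius: the
#' lateral surface of the lumen then coincides with the lateral wall, which
#' is what a rater traces. The tube covers the basal `theta_max_deg` of the
#' spiral (the default preset's apical radius is too small to host a
#' non-self-intersecting tube over the last ~120 degrees, mirroring how the
#' apical wall is also hardest to segment clinically).
#'
#' @param spiral A [make_spiral()] result.
#' @param spacing Voxel spacing (mm).
#' @param theta_max_deg Angular extent of the phantom.
#' @param lumen_radius Profile function of theta (mm).
#' @param shell_mm Bone shell thickness (mm).
#' @param preset Intensity preset, see [rasterize_to_volume()].
#' @return A `voxel_phantom` with attribute `theta_max_deg`.
#' @export
phantom_from_spiral <- function(spiral, spacing = 0.2, theta_max_deg = 780,
                                lumen_radius = lumen_radius_default,
                                shell_mm = 0.6, preset = "HRCT") {
  stopifnot(inherits(spiral, "cochlear_spiral"))
  th <- seq(0, min(theta_max_deg, spiral$params$turns_deg), by = 0.25)
  LW <- spiral$curve(th)
  lr <- lumen_radius(th)
  rad <- sqrt(LW[, 1]^2 + LW[, 2]^2)
  if (any(rad <= lr)) {
    stop_cdl("lumen radius exceeds wall radius: tube would cross the axis", "generation")
  }
  f <- (rad - lr) / rad
  C <- cbind(LW[, 1] * f, LW[, 2] * f, LW[, 3])
  ph <- rasterize_to_volume(C,
    lumen_radius = lr, spacing = spacing,
    shell_mm = shell_mm, preset = preset
  )
  attr(ph, "theta_max_deg") <- max(th)
  attr(ph, "lumen_seed") <- C[1, ]
  ph
}

#' Extract lateral-wall points from a segmented boundary
#'
#' Converts the boundary cloud of a segmented cochlea phantom into an
#' ordered lateral-wall point set: boundary points are windowed around the
#' expected wall (radius within `band_mm`, height within `z_band_mm` of the
#' generating spiral's profile — the synthetic analogue of a rater clicking
#' on the wall), and the lateral-most voxels of each angular bin are
#' averaged into one wall point. Boundary voxel centers lie strictly inside
#' the lumen, so the extracted wall sits slightly medial of the true wall:
#' the voxel-size-dependent shrinkage that motivates the 10/9 correction.
#'
#' @param boundary Tibble of boundary points from [threshold_segment()].
#' @param spiral The generating [make_spiral()] spiral (profile prior).
#' @param theta_max_deg Angular extent to extract.
#' @param bin_deg Angular bin width.
#' @param band_mm,z_band_mm Acceptance bands around the expected profile.
#' @param tol_mm Radial tolerance when averaging the lateral-most voxels.
#' @return An [lateral_wall_cloud()] ordered by angle (RW bin first).
#' @export
extract_lateral_wall <- function(boundary, spiral, theta_max_deg = 780,
                                 bin_deg = 5, band_mm = 0.3, z_band_mm = 0.75,
                                 tol_mm = 0.12) {
  stopifnot(inherits(spiral, "cochlear_spiral"))
  dth <- seq(0, min(theta_max_deg + bin_deg, spiral$params$turns_deg), by = 0.1)
  D <- spiral$curve(dth)
  phi <- unwrap_degrees(atan2(D[, 2], D[, 1]) * 180 / pi)
  rho <- sqrt(D[, 1]^2 + D[, 2]^2)
  f_r <- approxfun(phi, rho, rule = 2)
  f_z <- approxfun(phi, D[, 3], rule = 2)

  p <- atan2(boundary$y, boundary$x) * 180 / pi
  r <- sqrt(boundary$x^2 + boundary$y^2)
  sel <- list()
  for (k in 0:ceiling(theta_max_deg / 360)) {
    phk <- (p %% 360) + k * 360
    ok <- phk >= min(phi) & phk <= max(phi) &
      abs(r - f_r(phk)) < band_mm &
      abs(boundary$z - f_z(phk)) < z_band_mm
    if (any(ok)) {
      sel[[length(sel) + 1L]] <- tibble::tibble(
        theta = phk[ok], r = r[ok], z = boundary$z[ok]
      )
    }
  }
  pts <- dplyr::bind_rows(sel)
  if (nrow(pts) == 0L) stop_cdl("no boundary points near the expected wall", "segmentation")

  wall <- pts |>
    dplyr::mutate(bin = floor(.data$theta / bin_deg)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::filter(.data$r >= max(.data$r) - tol_mm) |>
    dplyr::summarise(
      theta = mean(.data$theta), r = max(.data$r), z = mean(.data$z),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$theta)
  lateral_wall_cloud(tibble::tibble(
    x = wall$r * cos(wall$theta * pi / 180),
    y = wall$r * sin(wall$theta * pi / 180),
    z = wall$z
  ))
}

#' Write / read a voxel phantom as raw binary + JSON header
#'
#' The volume is stored as little-endian 32-bit integers with a sidecar JSON
#' header (dims, spacing, origin, preset, window).
#'
#' @param phantom A `voxel_phantom`.
#' @param path Base path; `.raw` and `.json` are appended.
#' @return `path` (write) or a `voxel_phantom` (read).
#' @export
write_phantom <- function(phantom, path) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  hdr <- list(
    dims = dim(phantom$vol), spacing = phantom$spacing,
    origin = c(phantom$xs[1], phantom$ys[1], phantom$zs[1]),
    dtype = "int32", preset = phantom$preset, window = phantom$window
  )
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  con <- file(paste0(path, ".raw"), "wb")
  on.exit(close(con))
  writeBin(as.integer(phantom$vol), con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(hdr$dims)
  con <- file(paste0(path, ".raw"), "rb")
  on.exit(close(con))
  v <- readBin(con, "integer", n = n, size = 4L, endian = "little")
  structure(
    list(
      vol = array(v, hdr$dims),
      xs = hdr$origin[1] + (seq_len(hdr$dims[1]) - 1) * hdr$spacing,
      ys = hdr$origin[2] + (seq_len(hdr$dims[2]) - 1) * hdr$spacing,
      zs = hdr$origin[3] + (seq_len(hdr$dims[3]) - 1) * hdr$spacing,
      spacing = hdr$spacing, preset = hdr$preset, window = hdr$window
    ),
    class = "voxel_phantom"
  )
}
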