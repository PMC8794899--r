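# Geometric fixtures built in code: exact clouds with known closed forms.

circle_cloud <- function(r = 4.5, n = 80, z = 0) {
  th <- seq(0, 360, length.out = n + 1)[-(n + 1)]
  lateral_wall_cloud(tibble::tibble(
    x = r * cos(th * pi / 180), y = r * sin(th * pi / 180), z = z
  ))
}

ellipse_cloud <- function(a = 5, b = 3.5, n = 200) {
  th <- seq(0, 360, length.out = n + 1)[-(n + 1)]
  lateral_wall_cloud(tibble::tibble(
    x = a * cos(th * pi / 180), y = b * sin(th * pi / 180), z = 0
  ))
}

helix_cloud <- function(r = 3, pitch_per_deg = 4 / 900, turns_deg = 900, n = 500) {
  th <- seq(0, turns_deg, length.out = n)
  lateral_wall_cloud(tibble::tibble(
    x = r * cos(th * pi / 180), y = r * sin(th * pi / 180), z = pitch_per_deg * th
  ))
}

rand_rotation <- function(seed) {
  withr::with_seed(seed, {
    M <- matrix(rnorm(9), 3)
    R <- qr.Q(qr(M))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    R
  })
}

default_spiral <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_spiral()
    cache
  }
})

# dense polyline arc-length oracle on a spiral over [t1, t2] degrees
polyline_cdl <- function(spiral, t1, t2, step = 0.005) {
  P <- spiral$curve(seq(t1, t2, by = step))
  sum(sqrt(rowSums(diff(P)^2)))
}

canonical_cloud <- function(spiral = default_spiral(), n = 500) {
  sample_point_cloud(spiral, n = n, noise_sd = 0, seed = 1)
}
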