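test_that("a degenerate circle preset has closed-form ground truth", {
  sp <- make_spiral(spiral_params(
    r0 = 3, decay = 0, ellipticity = 0, height_mm = 0, turns_deg = 360
  ))
  expect_equal(sp$truth$full_cdl_mm, 2 * pi * 3, tolerance = 1e-6)
  expect_equal(sp$truth$A_mm, 6)
  expect_equal(sp$truth$B_mm, 6)
  expect_equal(sp$truth$H_mm, 0)
})

test_that("the default preset sits in the clinically reported ranges", {
  sp <- default_spiral()
  expect_gt(sp$truth$full_cdl_mm, 38)
  expect_lt(sp$truth$full_cdl_mm, 46)
  expect_gt(sp$truth$A_mm, 8.5)
  expect_lt(sp$truth$A_mm, 10.5)
})

test_that("scaling r0 scales the arc length linearly", {
  a <- make_spiral(spiral_params(r0 = 4, decay = 0, ellipticity = 0, height_mm = 0))
  b <- make_spiral(spiral_params(r0 = 2, decay = 0, ellipticity = 0, height_mm = 0))
  expect_equal(a$truth$full_cdl_mm / 2, b$truth$full_cdl_mm, tolerance = 1e-9)
})

test_that("ground-truth integration is converged", {
  sp <- default_spiral()
  # refine the polyline step 10x: the full CDL moves by far less than 1e-6 mm
  coarse <- polyline_cdl(sp, 0, 900, step = 0.01)
  fine <- polyline_cdl(sp, 0, 900, step = 0.001)
  expect_lt(abs(coarse - fine), 1e-6)
  # cdl_lw is monotone and ends at the full CDL
  th <- seq(0, 900, by = 50)
  v <- sp$truth$cdl_lw(th)
  expect_true(all(diff(v) > 0))
  expect_equal(sp$truth$cdl_lw(900), sp$truth$full_cdl_mm)
})

test_that("point-cloud sampling is exact at zero noise and seed-reproducible", {
  sp <- default_spiral()
  cl0 <- sample_point_cloud(sp, n = 50, noise_sd = 0, seed = 5)
  th <- seq(0, 900, length.out = 50)
  expect_equal(as.matrix(tibble::as_tibble(cl0)), sp$curve(th), ignore_attr = TRUE)
  c1 <- sample_point_cloud(sp, n = 100, noise_sd = 0.2, seed = 9)
  c2 <- sample_point_cloud(sp, n = 100, noise_sd = 0.2, seed = 9)
  c3 <- sample_point_cloud(sp, n = 100, noise_sd = 0.2, seed = 10)
  expect_identical(as.matrix(tibble::as_tibble(c1)), as.matrix(tibble::as_tibble(c2)))
  expect_false(identical(
    as.matrix(tibble::as_tibble(c1)),
    as.matrix(tibble::as_tibble(c3))
  ))
})

test_that("measurement simulation reproduces truth exactly at zero noise", {
  truth <- c(TBa = 40, TBb = 42.5)
  model <- measurement_error_model(
    bias_mm = rep(0, 6), noise_sd_mm = rep(0, 6),
    rater_sd_mm = 0, reference_sd_mm = 0
  )
  tab <- simulate_measurements(truth, model, raters = 2, seed = 1)
  expect_equal(tab$cdl_mm, unname(truth[tab$specimen_id]))
})

test_that("a pure construction bias appears as the exact mean difference", {
  truth <- setNames(rnorm(10, 42, 2), sprintf("TB%02d", 1:10))
  model <- measurement_error_model(
    bias_mm = rep(5, 6), noise_sd_mm = rep(0, 6),
    rater_sd_mm = 0, reference_sd_mm = 0
  )
  tab <- simulate_measurements(truth, model, raters = 1, seed = 2)
  d <- dunnett_vs_control(tab, control = "reference")
  expect_equal(d$mean_difference, rep(5, 6), tolerance = 1e-12)
})

test_that("two-rater ICC recovers the variance-component truth", {
  # specimen SD 2, rater noise SD 1 -> population ICC = 4 / (4 + 1) = 0.8;
  # at this n the ICC sampling SD is ~0.016, so +-0.05 is a three-sigma band
  n <- 1000
  truth <- withr::with_seed(8, setNames(rnorm(n, 42, 2), sprintf("S%03d", seq_len(n))))
  model <- measurement_error_model(
    methods = "M", bias_mm = 0, noise_sd_mm = 0,
    rater_sd_mm = 1, reference_sd_mm = 0
  )
  tab <- withr::with_seed(42, simulate_measurements(truth, model, raters = 2, seed = 7))
  fit <- icc_agreement(dplyr::filter(tab, method == "M"))
  expect_equal(fit$icc, 0.8, tolerance = 0.05)
})

test_that("cohorts are deterministic given the seed and exercise the pipeline", {
  a <- generate_cohort(4, seed = 123, include_clouds = FALSE)
  b <- generate_cohort(4, seed = 123, include_clouds = FALSE)
  expect_identical(a$measurements, b$measurements)
  expect_identical(a$truths, b$truths)
  expect_error(generate_cohort(1), class = "cdlkit_input")
  s <- summarize_methods(a$measurements)
  expect_setequal(
    s$method,
    c("3D-HRCT", "3D-CBCT", "A-HRCT", "A-CBCT", "SW-HRCT", "SW-CBCT", "reference")
  )
})
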