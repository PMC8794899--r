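test_that("the A-value formula reproduces its closed-form values", {
  expect_equal(cdl_escude(9, 0)$cdl_mm, 0)
  expect_equal(cdl_escude(9, 900)$cdl_mm, 2.62 * 9 * log(1 + 900 / 235))
  expect_equal(round(cdl_escude(9, 900)$cdl_mm, 2), 37.13)
  expect_equal(cdl_escude(9, 360)$cdl_mm, 2.62 * 9 * log(1 + 360 / 235))
  expect_equal(round(cdl_escude(9, 360)$cdl_mm, 2), 21.91)
  expect_error(cdl_escude(-1, 900), class = "cdlkit_domain")
  expect_error(cdl_escude(9, -5), class = "cdlkit_domain")
})

test_that("full-insertion A-value: exact mode equals theta = 900, printed mode truncates", {
  expect_equal(cdl_escude_full(9)$cdl_mm, cdl_escude(9, 900)$cdl_mm)
  expect_identical(cdl_escude_full(7.3)$cdl_mm - cdl_escude(7.3, 900)$cdl_mm, 0)
  expect_equal(cdl_escude_full(9, mode = "printed_constant")$cdl_mm, 37.0206)
  d <- cdl_escude_full(10)$cdl_mm - cdl_escude_full(10, mode = "printed_constant")$cdl_mm
  expect_equal(d, 0.125, tolerance = 1e-2)
  expect_equal(d, 26.2 * (log(1 + 900 / 235) - 1.57))
})

test_that("the elliptic-circular bracket is computed exactly as written", {
  bracket <- function(A, B) 1.18 * (A - 0.7) + 2.69 * (B - 0.7) - sqrt(0.72 * (A - 0.7) * (B - 0.7))
  expect_equal(cdl_elliptic(9, 6.5, theta = 360)$cdl_mm, bracket(9, 6.5))
  expect_equal(round(cdl_elliptic(9, 6.5, theta = 360)$cdl_mm, 4), 19.5087)
  # at A = B the bracket collapses to its closed form
  expect_equal(
    cdl_elliptic(7.7, 7.7, theta = 360)$cdl_mm,
    7 * (1.18 + 2.69) - 7 * sqrt(0.72)
  )
  # swapping A and B changes the value unless A = B
  expect_false(isTRUE(all.equal(
    cdl_elliptic(9, 6.5, 360)$cdl_mm, cdl_elliptic(6.5, 9, 360)$cdl_mm
  )))
  # offsets vanish at the 0.7 boundary
  eps <- 1e-9
  expect_lt(cdl_elliptic(0.7 + eps, 0.7 + eps, theta = 360)$cdl_mm, 1e-7)
  expect_error(cdl_elliptic(0.7, 5), class = "cdlkit_domain")
  expect_error(cdl_elliptic(9, 0.5), class = "cdlkit_domain")
})

test_that("pBTL profile is positive, non-decreasing and 1 at a full basal turn", {
  th <- seq(10, 990, by = 10)
  v <- pbtl_escude(th)
  expect_true(all(v > 0))
  expect_true(all(diff(v) > 0))
  expect_equal(pbtl_escude(360), 1)
  # a custom profile can be injected
  est <- cdl_elliptic(9, 6.5, theta = 720, pbtl = function(theta) 2)
  expect_equal(est$cdl_mm, 2 * cdl_elliptic(9, 6.5, 360)$cdl_mm)
})

test_that("both formula estimators are strictly increasing in their inputs", {
  A <- seq(5, 13, by = 0.01)
  expect_true(all(diff(cdl_escude(A, 900)$cdl_mm) > 0))
  th <- seq(0, 990, by = 1)
  expect_true(all(diff(cdl_escude(9, th)$cdl_mm) > 0))
  # bracket increasing in A at several fixed B, and in B at several fixed A
  for (B in c(5, 8, 13)) {
    expect_true(all(diff(cdl_elliptic(A, B, 360)$cdl_mm) > 0))
  }
  B <- seq(5, 13, by = 0.01)
  for (A1 in c(5, 8, 13)) {
    expect_true(all(diff(cdl_elliptic(A1, B, 360)$cdl_mm) > 0))
  }
})

test_that("surface and resolution corrections are recorded, guarded and inverse", {
  lw <- new_cdl_estimate(40, "elliptic_SW", 900)
  oc <- to_organ_of_corti(lw)
  expect_equal(oc$cdl_mm, 36)
  expect_equal(oc$surface, "organ_of_corti")
  expect_error(to_organ_of_corti(oc), class = "cdlkit_double_correction")
  # 0.9 then 10/9 is the identity
  back <- apply_resolution_correction(oc)
  expect_equal(back$cdl_mm, 40, tolerance = 1e-12)
  expect_error(apply_resolution_correction(back), class = "cdlkit_double_correction")
  # corrections commute
  a <- apply_resolution_correction(to_organ_of_corti(lw))
  b <- to_organ_of_corti(apply_resolution_correction(lw))
  expect_equal(a$cdl_mm, b$cdl_mm, tolerance = 1e-12)
  expect_equal(apply_resolution_correction(new_cdl_estimate(36, "A_value", 900))$cdl_mm, 40)
  expect_equal(apply_resolution_correction(new_cdl_estimate(38.2, "A_value", 900))$cdl_mm,
    42.444,
    tolerance = 1e-3
  )
})

test_that("coverage, insertion angle and reference CDL are mutually inverse", {
  el <- electrode_spec(31.5)
  expect_equal(predict_cc(31.5, el), 100)
  expect_equal(predict_cc(42, el), 75)
  expect_equal(round(predict_cc(43.2, el), 2), 72.92)
  expect_equal(predict_ia(100), 900)
  expect_equal(predict_ia(75), 675)
  expect_equal(predict_ia(74), 666)
  expect_equal(cdl_reference_from_ia(900, el)$cdl_mm, 31.5)
  expect_equal(cdl_reference_from_ia(675, el)$cdl_mm, 42)
  expect_equal(cdl_reference_from_ia(663.3, el)$cdl_mm, 31.5 * 900 / 663.3)
  expect_equal(round(cdl_reference_from_ia(663.3, el)$cdl_mm, 3), 42.741)
  # round trip at 1e-12 for arbitrary lengths
  for (L in c(0.5, 20, 31.5, 38.7, 44.1, 90)) {
    back <- cdl_reference_from_ia(predict_ia(predict_cc(L, el)), el)$cdl_mm
    expect_equal(back, L, tolerance = 1e-12)
  }
  expect_error(predict_cc(0), class = "cdlkit_domain")
  expect_error(predict_ia(-3), class = "cdlkit_domain")
  expect_error(cdl_reference_from_ia(0), class = "cdlkit_domain")
})

test_that("estimates carry method, theta, surface and corrections metadata", {
  est <- cdl_escude(9, 900)
  expect_s3_class(est, "cdl_estimate")
  expect_equal(est$method, "A_value")
  expect_equal(est$theta_deg, 900)
  expect_equal(est$surface, "lateral_wall")
  expect_equal(est$corrections, "")
  sw <- to_organ_of_corti(cdl_elliptic(9, 6.5))
  expect_equal(sw$corrections, "oc_0.9")
})
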