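test_that("MTV is exact voxel-count arithmetic", {
  m8 <- lesion_mask(array(rep(c(TRUE, FALSE), c(8, 19)), c(3, 3, 3)))
  expect_identical(mtv(m8), 8 * 0.125)
  single <- lesion_mask(array(c(TRUE, rep(FALSE, 26)), c(3, 3, 3)))
  expect_identical(mtv(single), 0.125)
  expect_error(mtv(lesion_mask(array(FALSE, c(3, 3, 3)))), "empty")
  # digitized 4 mm-radius sphere vs analytic 268.08 mm^3
  sph <- sphere_mask(n = 32, radius = 4)
  expect_lt(abs(mtv(sph) - 4 / 3 * pi * 64) / (4 / 3 * pi * 64), 0.03)
})

test_that("sphere-equivalent diameter inverts the sphere volume", {
  expect_equal(sphere_equivalent_diameter(pi / 6), 1)
  expect_equal(sphere_equivalent_diameter(0.125), 0.6203505, tolerance = 1e-6)
  expect_equal(sphere_equivalent_diameter(65.44985), 5, tolerance = 1e-5)
  expect_error(sphere_equivalent_diameter(0), "positive")
  expect_error(sphere_equivalent_diameter(-3), "positive")
})

test_that("RC lookup reproduces the calibration table and its edge rules", {
  tab <- rc_table()
  expect_identical(vapply(1:5, rc_lookup, numeric(1), table = tab),
                   c(0.04, 0.19, 0.41, 0.54, 0.70))
  expect_identical(rc_lookup(6, tab), 1.0)
  expect_identical(rc_lookup(5.001, tab), 1.0)
  expect_equal(rc_lookup(2.5, tab), 0.30)      # linear midpoint of 0.19/0.41
  expect_warning(rc05 <- rc_lookup(0.5, tab), "clamping")
  expect_identical(rc05, 0.04)
  expect_error(rc_lookup(-1, tab), "positive")
})

test_that("RC lookup is monotone non-decreasing in diameter", {
  tab <- rc_table()
  d <- seq(1, 8, by = 0.01)
  rc <- vapply(d, rc_lookup, numeric(1), table = tab)
  expect_true(all(diff(rc) >= 0))
})

test_that("rc_table validates its invariants", {
  expect_error(rc_table(1:3, c(0.2, 0.1, 0.3)), "increasing")
  expect_error(rc_table(c(1, 1, 2), c(0.1, 0.2, 0.3)), "increasing")
  expect_error(rc_table(1:2, c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("SUV correction divides by the recovery coefficient", {
  expect_identical(correct_suv(1.0, 1.0), 1.0)
  expect_equal(correct_suv(0.2, 0.41), 0.4878049, tolerance = 1e-6)
  expect_identical(correct_suv(2.0, 0.04), 50.0)
  expect_error(correct_suv(1, 0), "coefficient")
  expect_error(correct_suv(1, 1.5), "coefficient")
})

test_that("TLG is the exact product of SUVmean and MTV", {
  expect_identical(tlg(2, 10), 20)
  expect_identical(tlg(0, 123.4), 0)
  expect_error(tlg(1, 0), "positive|finite")
})

test_that("quantify assembles consistent metrics and applies the RC when eligible", {
  # uniform sphere phantom with d_equiv near 4 mm -> RC 0.54 row regime
  ph <- make_phantom(small_spec(radius = 2, suv = 2))
  mask <- segment_mtv(ph$image, small_bbox())
  met <- quantify(ph$image, mask)
  expect_equal(met$mtv_mm3, sum(mask$voxels) * 0.125)
  expect_lte(met$suv_mean, met$suv_max)
  expect_identical(met$tlg, met$suv_mean_corrected * met$mtv_mm3)
  expect_gte(met$suv_mean_corrected, met$suv_mean)
  expect_equal(met$rc_applied,
               rc_lookup(sphere_equivalent_diameter(met$mtv_mm3)))
  expect_equal(met$rc_applied, 0.54, tolerance = 0.03)
  # uncorrected TLG variant
  met_u <- quantify(ph$image, mask, use_corrected_for_tlg = FALSE)
  expect_identical(met_u$tlg, met_u$suv_mean * met_u$mtv_mm3)
})

test_that("quantify skips the correction with a warning when QC fails", {
  neg <- make_qc_negative("elongated", small_spec(radius = 2.5, suv = 2))
  q <- qc_report(neg$image, neg$mask)
  expect_warning(met <- quantify(neg$image, neg$mask, q), "QC")
  expect_identical(met$rc_applied, 1.0)
  expect_identical(met$suv_mean_corrected, met$suv_mean)
})

test_that("RC correction moves SUVmean toward truth for blurred small lesions", {
  # partial-volume direction: for every lesion at or below the table range,
  # dividing by the RC must reduce the error against true uptake
  for (d in c(2.5, 3.5, 4.5)) {
    ph <- make_phantom(small_spec(radius = d / 2, suv = 2))
    mask <- segment_mtv(ph$image, small_bbox())
    met <- suppressWarnings(quantify(ph$image, mask))
    true_suv <- ph$truth[[1]]$suv_mean
    expect_lt(abs(met$suv_mean_corrected - true_suv),
              abs(met$suv_mean - true_suv))
  }
})
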