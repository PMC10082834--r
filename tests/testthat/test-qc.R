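test_that("principal diameters recover analytic extents", {
  sph <- sphere_mask(n = 32, radius = 4)
  dd <- principal_diameters(sph)
  expect_equal(unname(dd["d_max"]), 8, tolerance = 0.5 / 8)   # within one voxel
  expect_equal(unname(dd["d_min"]), 8, tolerance = 0.5 / 8)

  ell <- ellipsoid_mask(n = 64, semi = c(6, 3, 3))
  de <- principal_diameters(ell)
  expect_equal(unname(de["d_max"]), 12, tolerance = 0.06)
  expect_equal(unname(de["d_min"]), 6, tolerance = 0.12)

  single <- lesion_mask(array(c(TRUE, rep(FALSE, 26)), c(3, 3, 3)))
  expect_equal(unname(principal_diameters(single)), c(0.5, 0.5))
})

test_that("sphericity gate is strict at 50%", {
  expect_true(sphericity_check(diameters = c(12, 6.1))$is_spherical)
  s50 <- sphericity_check(diameters = c(12, 6))
  expect_equal(s50$sphericity_pct, 50)
  expect_false(s50$is_spherical)      # exactly 50 fails
  s625 <- sphericity_check(diameters = c(16, 6))
  expect_equal(s625$sphericity_pct, 62.5)
  expect_false(s625$is_spherical)
  sph <- sphericity_check(sphere_mask(n = 32, radius = 4))
  expect_lt(sph$sphericity_pct, 10)
  expect_true(sph$is_spherical)
})

test_that("sphericity is invariant under rotation and isotropic scaling", {
  ax <- sphericity_check(ellipsoid_mask(n = 64, semi = c(6, 3, 3)))
  rot <- sphericity_check(rotated_ellipsoid_mask(n = 64, semi = c(6, 3, 3),
                                                 theta = pi / 6))
  expect_equal(ax$sphericity_pct, rot$sphericity_pct, tolerance = 0.05)
  big <- sphericity_check(ellipsoid_mask(n = 96, semi = 1.5 * c(6, 3, 3)))
  expect_equal(ax$sphericity_pct, big$sphericity_pct, tolerance = 0.05)
})

test_that("uniformity flags single-population lesions as uniform", {
  mk <- sphere_mask(n = 24, radius = 3)
  # constant lesion
  a <- array(0, c(24, 24, 24)); a[mk$voxels] <- 2
  expect_identical(uniformity_check(suv_from_array(a), mk)$peak_count, 1L)
  # one Gaussian population, sigma small vs range
  set.seed(3)
  b <- array(0, c(24, 24, 24))
  b[mk$voxels] <- rnorm(sum(mk$voxels), mean = 2, sd = 0.08)
  u <- uniformity_check(suv_from_array(b), mk)
  expect_true(u$is_uniform)
  # blurred uniform sphere (the canonical eligible lesion)
  ph <- make_phantom(small_spec(radius = 2.5, suv = 2))
  m <- segment_mtv(ph$image, small_bbox())
  expect_true(uniformity_check(ph$image, m)$is_uniform)
})

test_that("uniformity flags separated uptake populations", {
  mk <- sphere_mask(n = 24, radius = 3)
  nvox <- sum(mk$voxels)
  a <- array(0, c(24, 24, 24))
  a[mk$voxels] <- rep(c(1, 5), length.out = nvox)
  u <- uniformity_check(suv_from_array(a), mk)
  expect_identical(u$peak_count, 2L)
  expect_false(u$is_uniform)
  # the literal histogram method agrees on this construction
  uh <- uniformity_check(suv_from_array(a), mk, method = "histogram")
  expect_identical(uh$peak_count, 2L)
})

test_that("uniformity verdict is invariant under affine SUV rescaling", {
  mk <- sphere_mask(n = 24, radius = 3)
  set.seed(5)
  base <- rnorm(sum(mk$voxels), 2, 0.1)
  bimo <- c(rnorm(ceiling(sum(mk$voxels) / 2), 1, 0.05),
            rnorm(floor(sum(mk$voxels) / 2), 4, 0.05))
  for (vals in list(base, bimo)) {
    a <- array(0, c(24, 24, 24)); a[mk$voxels] <- vals
    v0 <- uniformity_check(suv_from_array(a), mk)
    a2 <- array(0, c(24, 24, 24)); a2[mk$voxels] <- 3 * vals + 7
    v1 <- uniformity_check(suv_from_array(a2), mk)
    expect_identical(v0$peak_count, v1$peak_count)
  }
})

test_that("qc_report gates PVE eligibility on both checks", {
  # spherical + uniform -> eligible
  ph <- make_phantom(small_spec(radius = 2.5, suv = 2))
  m <- segment_mtv(ph$image, small_bbox())
  q <- qc_report(ph$image, m)
  expect_true(q$is_spherical && q$is_uniform && q$pve_eligible)

  # elongated lesion: sphericity fails, uniformity passes
  neg <- make_qc_negative("elongated", small_spec(radius = 2.5, suv = 2))
  qe <- qc_report(neg$image, neg$mask)
  expect_false(qe$is_spherical)
  expect_true(qe$is_uniform)
  expect_false(qe$pve_eligible)

  # bimodal lesion: uniformity fails, sphericity passes
  negb <- make_qc_negative("bimodal", small_spec(radius = 2.5, suv = 2))
  qb <- qc_report(negb$image, negb$mask)
  expect_true(qb$is_spherical)
  expect_false(qb$is_uniform)
  expect_false(qb$pve_eligible)
})
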