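test_that("find_max_suv_slice locates the hottest slice with low-index ties", {
  a <- array(0, c(12, 12, 12))
  a[7, 5, 5] <- 3
  img <- suv_from_array(a)
  bb <- bbox3d(c(2, 12), c(2, 12), c(2, 12))
  expect_identical(find_max_suv_slice(img, bb)$slice_index, 7L)

  a2 <- array(0, c(12, 12, 12))
  a2[3, 6, 6] <- 2; a2[9, 4, 4] <- 2
  expect_identical(find_max_suv_slice(suv_from_array(a2), bb)$slice_index, 3L)

  a3 <- array(0, c(12, 12, 12))
  a3[4:10, 4:10, 4:10] <- 1   # uniform box: lowest axial index of the bbox
  bb2 <- bbox3d(c(4, 10), c(4, 10), c(4, 10))
  expect_identical(find_max_suv_slice(suv_from_array(a3), bb2)$slice_index, 4L)

  expect_error(find_max_suv_slice(suv_from_array(array(0, c(12, 12, 12))), bb),
               "degenerate")
  expect_error(find_max_suv_slice(suv_from_array(a), bbox3d(c(1, 20), c(1, 12), c(1, 12))),
               "outside")
})

test_that("region growing on a uniform disk equals the thresholding oracle", {
  a <- array(0, c(9, 32, 32))
  yy <- outer((seq_len(32) - 16)^2, (seq_len(32) - 16)^2, "+")
  disk <- yy <= 36
  a[5, , ][disk] <- 1
  img <- suv_from_array(a)
  bb <- bbox3d(c(2, 9), c(2, 32), c(2, 32))
  seed <- find_max_suv_slice(img, bb)
  ct <- region_grow_2d(img, seed)
  expect_identical(ct$mask2d, disk)

  # single hot voxel: the contour is exactly that voxel
  a1 <- array(0, c(9, 32, 32)); a1[5, 10, 20] <- 2
  ct1 <- region_grow_2d(img1 <- suv_from_array(a1), find_max_suv_slice(img1, bb))
  expect_identical(which(ct1$mask2d), which(a1[5, , ] > 0))

  # two disks separated by zeros: only the seeded one is grown
  a2 <- array(0, c(9, 32, 32))
  diskA <- outer((seq_len(32) - 9)^2, (seq_len(32) - 9)^2, "+") <= 16
  diskB <- outer((seq_len(32) - 24)^2, (seq_len(32) - 24)^2, "+") <= 16
  a2[5, , ][diskA] <- 2; a2[5, , ][diskB] <- 1.5
  img2 <- suv_from_array(a2)
  ct2 <- region_grow_2d(img2, find_max_suv_slice(img2, bb))
  expect_identical(ct2$mask2d, diskA)
})

test_that("active surface recovers a uniform sphere within 5% and is a fixed point", {
  ph <- make_phantom(small_spec(radius = 2, suv = 2))
  bb <- small_bbox()
  seed <- find_max_suv_slice(ph$image, bb)
  init <- region_grow_2d(ph$image, seed)
  mask <- evolve_active_surface(ph$image, init, seed)
  truth <- ph$truth[[1]]
  expect_lt(abs(mtv(mask) - truth$volume_mm3) / truth$volume_mm3, 0.05)
  # one 26-connected component containing the bbox maximum
  expect_identical(petquant:::.count_components26(mask$voxels), 1L)
  expect_true(mask$voxels[seed$seed_vox[1], seed$seed_vox[2], seed$seed_vox[3]])
  # idempotence: re-evolving from the converged mask changes nothing
  sl <- mask$voxels[seed$slice_index, , ]
  ct_conv <- structure(list(slice_index = seed$slice_index, mask2d = sl,
                            seed_vox = seed$seed_vox), class = "contour2d")
  mask2 <- evolve_active_surface(ph$image, ct_conv, seed)
  expect_identical(mask2$voxels, mask$voxels)
})

test_that("a second hot sphere in the box is excluded from the mask", {
  sp <- phantom_spec(shape = c(64, 64, 64),
                     lesions = list(list(center_mm = c(12, 12, 12),
                                         radius_mm = 2.5, suv = 2),
                                    list(center_mm = c(22, 22, 22),
                                         radius_mm = 2, suv = 1.6)))
  ph <- make_phantom(sp)
  mask <- segment_mtv(ph$image, small_bbox())
  expect_identical(petquant:::.count_components26(mask$voxels), 1L)
  expect_true(all(mask$voxels[ph$truth[[2]]$mask$voxels] == FALSE))
  expect_gt(sum(mask$voxels & ph$truth[[1]]$mask$voxels), 0)
})

test_that("segmentation equals the thresholding oracle on crisp uniform objects", {
  # no blur, zero background: any positive threshold recovers the object
  sp <- small_spec(radius = 2.5, suv = 1, psf_sigma_mm = 0, background_suv = 0)
  ph <- make_phantom(sp)
  mask <- segment_mtv(ph$image, small_bbox())
  oracle <- ph$image$voxels >= 0.4 * max(ph$image$voxels)
  expect_identical(mask$voxels, oracle)
  expect_identical(mask$voxels, ph$truth[[1]]$mask$voxels)
})

test_that("the MTV is operator-independent and deterministic", {
  ph <- make_phantom(small_spec(radius = 2.5))
  m1 <- segment_mtv(ph$image, bbox3d(c(10, 55), c(10, 55), c(10, 55)))
  m2 <- segment_mtv(ph$image, bbox3d(c(16, 50), c(16, 50), c(16, 50)))
  expect_identical(m1$voxels, m2$voxels)
  m3 <- segment_mtv(ph$image, bbox3d(c(10, 55), c(10, 55), c(10, 55)))
  expect_identical(m1$voxels, m3$voxels)
})

test_that("degenerate inputs raise stage-appropriate errors", {
  z <- suv_from_array(array(0, c(16, 16, 16)))
  expect_error(segment_mtv(z, bbox3d(c(2, 15), c(2, 15), c(2, 15))),
               "degenerate")
  expect_error(segmentation_config(rg_fraction = 1.2), "rg_fraction")
  expect_error(segmentation_config(ac_max_iter = 0), "ac_max_iter")
})

test_that("mild background noise changes the recovered MTV by less than 10%", {
  clean <- make_phantom(small_spec(radius = 2.5, suv = 2))
  noisy <- make_phantom(small_spec(radius = 2.5, suv = 2, seed = 42L,
                                   noise = list(type = "gaussian", sd = 0.15)))
  v_clean <- mtv(segment_mtv(clean$image, small_bbox()))
  v_noisy <- mtv(segment_mtv(noisy$image, small_bbox()))
  expect_lt(abs(v_noisy - v_clean) / v_clean, 0.10)
})
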