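test_that("roi_voxels matches brute-force voxel-centre enumeration", {
  v <- ct_volume(array(0, c(9, 9, 9)), spacing = 1, origin = c(0, 0, 0))
  roi <- ellipsoid_roi(center = c(4, 4, 4), semi_axes = 1.5)
  got <- roi_voxels(v, roi)
  # oracle: enumerate the 5^3 neighbourhood around the centre
  inside <- NULL
  for (z in 0:8) for (y in 0:8) for (x in 0:8)
    if (sum(((c(z, y, x) - 4) / 1.5)^2) <= 1)
      inside <- rbind(inside, c(z + 1, y + 1, x + 1))
  expect_equal(nrow(got), 19L)   # centre + 6 faces + 12 edges at sqrt(2)
  expect_setequal(apply(got, 1, paste, collapse = ","),
                  apply(inside, 1, paste, collapse = ","))
})

test_that("degenerate and translated ROIs behave on the lattice", {
  v <- ct_volume(array(0, c(9, 9, 9)), spacing = 1, origin = c(0, 0, 0))
  tiny <- ellipsoid_roi(center = c(4, 4, 4), semi_axes = 0.4)
  expect_equal(nrow(roi_voxels(v, tiny)), 1L)
  r1 <- ellipsoid_roi(center = c(3, 4, 4), semi_axes = 1.5)
  expect_equal(nrow(roi_voxels(v, r1)), 19L)   # lattice translation symmetry
  outside <- ellipsoid_roi(center = c(100, 100, 100), semi_axes = 2)
  expect_error(roi_voxels(v, outside), "outside")
})

test_that("roi_stats equals brute-force arithmetic", {
  const <- ct_volume(array(-115, c(7, 7, 7)), spacing = 1)
  s <- roi_stats(const, ellipsoid_roi(c(0, 0, 0), 2))
  expect_equal(s$mean_hu, -115)
  expect_equal(s$sd_hu, 0)

  set.seed(5)
  vals <- array(rnorm(27, -100, 20), c(3, 3, 3))
  v <- ct_volume(vals, spacing = 1, origin = c(0, 0, 0))
  all_roi <- ellipsoid_roi(center = c(1, 1, 1), semi_axes = 3)
  s2 <- roi_stats(v, all_roi)
  expect_equal(s2$n_voxels, 27L)
  expect_equal(s2$mean_hu, mean(vals))
  expect_equal(s2$sd_hu, sd(as.vector(vals)))
})

test_that("calibrate_fat_hu averages ROI means and enforces the voxel floor", {
  const <- ct_volume(array(-115, c(24, 24, 24)), spacing = 0.125)
  one <- calibrate_fat_hu(const, ellipsoid_roi(c(0, 0, 0), 0.7), min_voxels = 400)
  expect_equal(one$value_hu, -115)

  set.seed(8)
  v <- ct_volume(array(rnorm(24^3, -115, 15), c(24, 24, 24)), spacing = 0.125)
  r1 <- ellipsoid_roi(c(-0.4, 0, 0), 0.6)
  r2 <- ellipsoid_roi(c(0.4, 0, 0), 0.6)
  m1 <- roi_stats(v, r1)$mean_hu
  m2 <- roi_stats(v, r2)$mean_hu
  cal <- calibrate_fat_hu(v, list(r1, r2))
  expect_equal(cal$value_hu_unrounded, (m1 + m2) / 2)
  # invariant to ROI ordering
  expect_equal(calibrate_fat_hu(v, list(r2, r1))$value_hu_unrounded,
               cal$value_hu_unrounded)
  # too-small ROI is refused by index
  expect_error(calibrate_fat_hu(v, list(r1, ellipsoid_roi(c(0, 0, 0), 0.2))),
               "ROI 2")
})

test_that("calibration on the ex-vivo phantom recovers the fat value", {
  vol <- make_exvivo_fat_phantom(seed = 12)
  rois <- default_calibration_rois(vol)
  expect_length(rois, 6L)
  cal <- calibrate_fat_hu(vol, rois)
  expect_true(all(cal$per_roi$n_voxels > 400))
  expect_equal(cal$value_hu, -115)
})

test_that("the calibrated value is unbiased across noise realisations", {
  vals <- vapply(1:60, function(s) {
    vol <- make_exvivo_fat_phantom(shape = c(32, 32, 32), seed = s)
    calibrate_fat_hu(vol, default_calibration_rois(vol, n = 4))$value_hu_unrounded
  }, numeric(1))
  expect_lt(abs(mean(vals) + 115), 1)
})

test_that("density windows validate and build from calibrations", {
  expect_error(density_window(50, -115), "lo")
  w <- build_fat_window(-115)
  expect_equal(c(w$lo, w$hi), c(-115, 50))
  w2 <- build_fat_window(-150, upper = 50)
  expect_equal(c(w2$lo, w2$hi), c(-150, 50))
  expect_error(build_fat_window(60), "lo")
  expect_equal(c(fat_window()$lo, fat_window()$hi), c(-115, 50))
  expect_equal(c(body_window()$lo, body_window()$hi), c(-1000, 2500))
})
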