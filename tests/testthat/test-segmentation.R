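test_that("segment_window equals the brute-force oracle on small volumes", {
  set.seed(2)
  for (rep in 1:3) {
    d <- sample(3:8, 3, replace = TRUE)
    data <- array(runif(prod(d), -1200, 2600), d)
    v <- ct_volume(data, spacing = 1)
    m <- segment_window(v, fat_window())
    expect_identical(m$data, brute_force_window(data, -115, 50))
    within <- array(runif(prod(d)) > 0.5, d)
    m2 <- segment_window(v, density_window(-300, 900), within = voxel_mask(within))
    expect_identical(m2$data, brute_force_window(data, -300, 900, within))
  }
})

test_that("window endpoints are inclusive on both sides", {
  data <- array(c(-115.0000001, -115, -114, 49, 50, 50.0000001, 0, -1000), c(2, 2, 2))
  m <- segment_window(ct_volume(data, 1), fat_window())
  expect_identical(as.vector(m$data),
                   c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE))
})

test_that("widening a window never shrinks the segmented set", {
  set.seed(4)
  data <- array(runif(10^3, -1200, 2600), c(10, 10, 10))
  v <- ct_volume(data, 1)
  for (rep in 1:5) {
    lo <- runif(1, -1000, 0); hi <- runif(1, 100, 2000)
    base <- segment_window(v, density_window(lo, hi))$data
    wider <- segment_window(v, density_window(lo - runif(1, 0, 300),
                                              hi + runif(1, 0, 300)))$data
    expect_true(all(wider[base]))
  }
})

test_that("bed masks come from threshold plus one-voxel dilation", {
  air <- ct_volume(array(-1000, c(6, 6, 6)), 1)
  expect_equal(n_voxels(bed_mask_from_empty_scan(air)), 0L)

  slab <- array(-1000, c(8, 6, 6))
  slab[2:3, , ] <- 300
  empty <- ct_volume(slab, 1)
  got <- bed_mask_from_empty_scan(empty)$data
  expect_identical(got, brute_force_dilate6(slab > -900))

  fish <- ct_volume(array(0, c(4, 4, 4)), 1)
  expect_error(segment_specimen(fish, c(2, 2, 2), empty = empty), "shape")
})

test_that("zero-noise phantoms are recovered exactly by the isocontour", {
  spec <- test_fish_spec(noise_sd = 0, blur_sigma = 0, seed = 2)
  ph <- make_fish_phantom(spec)
  empty <- make_empty_bed_scan(spec)
  seg <- segment_specimen(ph$volume, auto_seed_point(ph$volume), empty = empty)
  expect_equal(n_voxels(seg$body_mask), ph$truth$n_body)

  # with clean tissue separation the fat mask equals the label set exactly
  spec2 <- test_fish_spec(noise_sd = 0, blur_sigma = 0, seed = 2,
                          tissues = clean_tissues())
  ph2 <- make_fish_phantom(spec2)
  seg2 <- segment_specimen(ph2$volume, auto_seed_point(ph2$volume),
                           empty = make_empty_bed_scan(spec2))
  expect_identical(which(seg2$fat_mask$data), which(ph2$truth$labels == 2L))
})

test_that("noisy phantoms are recovered within the reference tolerance", {
  errs <- vapply(1:3, function(s) {
    spec <- test_fish_spec(seed = s)
    ph <- make_fish_phantom(spec)
    seg <- segment_specimen(ph$volume, auto_seed_point(ph$volume),
                            empty = make_empty_bed_scan(spec))
    abs(n_voxels(seg$body_mask) - ph$truth$n_body) / ph$truth$n_body
  }, numeric(1))
  expect_lt(max(errs), 0.02)
})

test_that("the isocontour is invariant to the seed voxel within the body", {
  spec <- test_fish_spec(seed = 5)
  ph <- make_fish_phantom(spec)
  empty <- make_empty_bed_scan(spec)
  s1 <- auto_seed_point(ph$volume)
  m1 <- segment_specimen(ph$volume, s1, empty = empty)$body_mask
  # a second seed: any other voxel already inside the recovered component
  idx <- which(m1$data, arr.ind = TRUE)
  s2 <- idx[nrow(idx) %/% 3, ]
  m2 <- segment_specimen(ph$volume, s2, empty = empty)$body_mask
  expect_identical(m1$data, m2$data)
})

test_that("segmentation invariants and contract errors hold", {
  spec <- test_fish_spec(seed = 6)
  ph <- make_fish_phantom(spec)
  empty <- make_empty_bed_scan(spec)
  seg <- segment_specimen(ph$volume, auto_seed_point(ph$volume), empty = empty)
  expect_true(all(seg$body_mask$data[seg$fat_mask$data]))       # fat inside body
  expect_false(any(seg$fat_mask$data & seg$bed_mask$data))      # fat disjoint from bed
  expect_error(body_isocontour(ph$volume, c(1, 1, 1)), "outside")    # air seed
  expect_error(body_isocontour(ph$volume, c(999, 1, 1)), "outside")  # out of grid
  expect_false(seg$qc$below_floor)
  # the QC floor flags implausibly small components
  tiny <- ct_volume(array(c(rep(0, 8), rep(-1000, 56)), c(4, 4, 4)), spacing = 2)
  m <- body_isocontour(tiny, c(1, 1, 1))
  expect_true(attr(m, "qc")$below_floor)
})
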