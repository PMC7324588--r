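test_that("zero-noise, zero-blur phantoms take exact tissue means", {
  spec <- test_fish_spec(noise_sd = 0, blur_sigma = 0)
  ph <- make_fish_phantom(spec)
  lab <- ph$truth$labels
  hu <- ph$volume$data
  tis <- tissue_table()
  for (tn in c("fat", "soft_tissue", "bone", "bed", "background_air")) {
    code <- tis$code[tis$tissue == tn]
    mean_hu <- tis$mean_hu[tis$tissue == tn]
    expect_true(all(hu[lab == code] == mean_hu), info = tn)
  }
})

test_that("ground truth is definitionally exact and near its targets", {
  spec <- test_fish_spec(target_fat_fraction = 48, seed = 2)
  ph <- make_fish_phantom(spec)
  tr <- ph$truth
  voxvol <- voxel_volume(ph$volume)
  expect_equal(tr$body_volume_cm3, tr$n_body * voxvol / 1000)
  expect_equal(tr$fat_volume_cm3, tr$n_fat * voxvol / 1000)
  expect_equal(tr$fat_fraction_pct, 100 * tr$fat_volume_cm3 / tr$body_volume_cm3)
  # auto-scaled depots hit the requested fraction well within 0.5 pp
  expect_lt(abs(tr$fat_fraction_pct - 48), 0.5)
  expect_lt(abs(tr$body_volume_cm3 - spec$total_volume_cm3), 0.05)
  # depots inside the body, bed strictly below it
  body <- tr$labels %in% c(1, 2, 3, 6)
  dim(body) <- dim(tr$labels)
  zmin_body <- min(which(apply(body, 1, any)))
  expect_true(max(tr$bed_layers) < zmin_body)
})

test_that("phantom generation is bitwise deterministic under a fixed seed", {
  spec <- test_fish_spec(seed = 9)
  a <- make_fish_phantom(spec)
  b <- make_fish_phantom(spec)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$labels, b$truth$labels)
  c2 <- make_fish_phantom(test_fish_spec(seed = 10))
  expect_false(identical(a$volume$data, c2$volume$data))
})

test_that("requested fractions that cannot fit raise errors", {
  expect_error(fish_phantom_spec(target_fat_fraction = 0), "target_fat_fraction")
  expect_error(fish_phantom_spec(target_fat_fraction = 100), "target_fat_fraction")
  expect_error(make_fish_phantom(test_fish_spec(target_fat_fraction = 99)),
               "cannot fit")
})

test_that("ex-vivo fat block has the configured attenuation statistics", {
  v0 <- make_exvivo_fat_phantom(sd_hu = 0, shape = c(24, 24, 24))
  block <- v0$data > -1000
  expect_true(all(v0$data[block] == -115))
  expect_true(any(block))

  v <- make_exvivo_fat_phantom(mean_hu = -115, sd_hu = 15,
                               shape = c(40, 40, 40), seed = 4)
  vals <- v$data[v$data > -500]
  expect_gt(length(vals), 1e4)
  expect_lt(abs(mean(vals) + 115), 3 * 15 / sqrt(length(vals)))

  v2 <- make_exvivo_fat_phantom(mean_hu = -115, sd_hu = 15,
                                shape = c(40, 40, 40), seed = 5)
  expect_false(identical(v$data, v2$data))
  vals2 <- v2$data[v2$data > -500]
  expect_lt(abs(mean(vals2) + 115), 3 * 15 / sqrt(length(vals2)))
})

test_that("cohorts reproduce their biometric parameterisation", {
  fed <- make_cohort("fed", n = 6, base_seed = 21)
  vols <- vapply(fed, function(p) p$truth$body_volume_cm3, numeric(1))
  expect_lt(abs(mean(vols) - 71.289), 3 * 0.655 / sqrt(6) + 0.05)

  starved <- make_cohort("starved", n = 6, base_seed = 22)
  fr <- vapply(starved, function(p) p$truth$fat_fraction_pct, numeric(1))
  expect_lt(abs(mean(fr) - 49.172), 3 * 3.080 / sqrt(6) + 0.1)

  meta <- fed[[1]]$meta
  expect_true(all(c("id", "condition", "weight_g", "length_cm") %in% names(meta)))
  expect_identical(meta$condition, "fed")

  again <- make_cohort("fed", n = 6, base_seed = 21)
  expect_identical(lapply(fed, function(p) p$volume$data),
                   lapply(again, function(p) p$volume$data))
  expect_error(make_cohort("fed", n = 1), ">= 2")
})

test_that("the empty-bed scan shares the phantom's bed geometry", {
  spec <- test_fish_spec(noise_sd = 0, blur_sigma = 0, seed = 3)
  ph <- make_fish_phantom(spec)
  empty <- make_empty_bed_scan(spec)
  bed_vox <- ph$truth$labels == 5
  expect_true(all(empty$data[bed_vox] == 300))
  expect_true(all(empty$data[!bed_vox] == -1000))
})
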