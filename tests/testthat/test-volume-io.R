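test_that("ct_volume validates its invariants and computes voxel volume", {
  v <- ct_volume(array(0, c(4, 5, 6)), spacing = 0.125)
  expect_equal(v$spacing, rep(0.125, 3))
  expect_equal(voxel_volume(v), 0.125^3)
  expect_error(ct_volume(array(0, c(4, 4)), 1), "3D")
  expect_error(ct_volume(array(0, c(4, 4, 4)), spacing = 0), "positive")
  expect_error(ct_volume(array(0, c(4, 4, 4)), spacing = c(1, -1, 1)), "positive")
  expect_error(ct_volume(array(NA_real_, c(2, 2, 2)), 1), "finite")
  flagged <- qc_hu_range(ct_volume(array(c(-2000, 0), c(2, 1, 1)), 1))
  expect_false(flagged$ok)
  expect_equal(flagged$n_outside, 1L)
  expect_true(qc_hu_range(ct_volume(array(-1000, c(2, 2, 2)), 1))$ok)
})

test_that("write/read round-trips data, spacing and origin for both formats", {
  set.seed(11)
  v <- ct_volume(array(rnorm(6 * 7 * 8, sd = 300), c(6, 7, 8)),
                 spacing = c(0.5, 0.25, 1.5), origin = c(-1, 2, 3.5))
  for (ext in c("nii.gz", "nii", "mha", "mhd")) {
    p <- file.path(tempdir(), paste0("roundtrip.", ext))
    write_volume(v, p)
    w <- read_volume(p)
    expect_equal(w$data, v$data, tolerance = 0, info = ext)
    expect_equal(w$spacing, v$spacing, tolerance = 1e-9, info = ext)
    expect_equal(w$origin, v$origin, tolerance = 1e-5, info = ext)
  }
})

test_that("masks round-trip as 0/1 volumes", {
  m <- voxel_mask(array(c(TRUE, FALSE), c(4, 4, 4)), "fat")
  p <- file.path(tempdir(), "mask.mha")
  write_volume(m, p)
  w <- read_volume(p)
  expect_identical(w$data == 1, m$data)
})

test_that("I/O contract violations raise explicit errors", {
  expect_error(read_volume(file.path(tempdir(), "nope.nii")), "exist")
  v <- ct_volume(array(0, c(2, 2, 2)), 1)
  expect_error(write_volume(v, file.path(tempdir(), "x.foo")), "format")
  expect_error(write_volume(v, "/nonexistent-dir/x.nii"), "directory")
  # MetaImage header without spacing must error, never assume 1 mm
  f <- file.path(tempdir(), "nospacing.mha")
  con <- file(f, "wb")
  writeLines(c("ObjectType = Image", "NDims = 3", "BinaryData = True",
               "DimSize = 2 2 2", "ElementType = MET_DOUBLE",
               "ElementDataFile = LOCAL"), con)
  writeBin(as.double(1:8), con, size = 8L, endian = "little")
  close(con)
  expect_error(read_volume(f), "spacing")
})

test_that("reduce_volume mean-pools, rescales spacing, drops partial blocks", {
  v <- ct_volume(array(-115, c(4, 4, 4)), spacing = 1)
  expect_identical(reduce_volume(v, 1), v)
  r <- reduce_volume(v, 2)
  expect_equal(dim(r$data), c(2L, 2L, 2L))
  expect_true(all(r$data == -115))
  expect_equal(r$spacing, rep(2, 3))

  v8 <- ct_volume(array(c(-1000, 0, 0, 0, 0, 0, 0, 2500), c(2, 2, 2)), 1)
  expect_equal(as.vector(reduce_volume(v8, 2)$data), 187.5)

  expect_error(reduce_volume(v, 0), "positive")
  expect_error(reduce_volume(v, -2), "positive")
})

test_that("reduction preserves block means and voxel-count scaling", {
  set.seed(7)
  a <- array(rnorm(12^3), c(12, 12, 12))
  v <- ct_volume(a, spacing = 0.5)
  for (f in c(2L, 3L)) {
    r <- reduce_volume(v, f)
    expect_equal(prod(dim(r$data)) * f^3, 12^3)
    expect_equal(mean(r$data), mean(a))                    # global mean conserved
    expect_equal(r$spacing, rep(0.5 * f, 3))
    # one specific block against hand pooling
    expect_equal(r$data[1, 1, 1], mean(a[1:f, 1:f, 1:f]))
    expect_equal(r$data[2, 1, 2], mean(a[(f + 1):(2 * f), 1:f, (f + 1):(2 * f)]))
  }
  # trailing partial blocks are dropped
  odd <- ct_volume(array(seq_len(5^3), c(5, 5, 5)), 1)
  r2 <- reduce_volume(odd, 2)
  expect_equal(dim(r2$data), c(2L, 2L, 2L))
  expect_equal(r2$data[1, 1, 1], mean(odd$data[1:2, 1:2, 1:2]))
})
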