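# NIfTI round trips, axial slice extraction and slice preprocessing.

test_that("phantom volumes and masks round-trip through NIfTI exactly", {
  cfg <- tiny_phantom_cfg()
  rec <- generatePhantom(cfg, 1L)
  td <- withr::local_tempdir()
  vp <- file.path(td, "v.nii.gz")
  mp <- file.path(td, "m.nii.gz")
  writeVolume(rec, vp)
  writeMask(rec, mp)
  back <- readVolume(vp, maskPath = mp)
  expect_equal(voxels(back), voxels(rec), tolerance = 1e-6)
  expect_equal(spacingMm(back), spacingMm(rec))
  expect_identical(sum(volMask(back)), sum(volMask(rec)))
  expect_true(all(volMask(back) == volMask(rec)))

  # reading the mask file as a volume: its voxel grid is the mask
  mrec <- readVolume(mp)
  expect_identical(sum(voxels(mrec) > 0.5), sum(volMask(rec) > 0.5))
})

test_that("a degenerate 1x1x1 volume survives the round trip", {
  rec <- volumeRecord(array(3.5, dim = c(1, 1, 1)), spacingMm = c(1, 1, 1))
  p <- withr::local_tempfile(fileext = ".nii.gz")
  writeVolume(rec, p)
  back <- readVolume(p)
  expect_equal(voxels(back), voxels(rec))
  expect_equal(spacingMm(back), c(1, 1, 1))
})

test_that("read/write error contracts are distinct and typed", {
  expect_error(readVolume(file.path(tempdir(), "nope.nii")),
               class = "cdseg_not_found")
  txt <- withr::local_tempfile(fileext = ".nii")
  writeLines("this is not a nifti file", txt)
  expect_error(readVolume(txt), class = "cdseg_invalid_volume")

  rec <- generatePhantom(tiny_phantom_cfg(), 2L)
  p <- withr::local_tempfile(fileext = ".nii")
  expect_error(writeMask(rec, p, mask = array(1, dim = c(2, 2, 2))),
               class = "cdseg_shape_mismatch")
  rec2 <- volumeRecord(array(0, dim = c(8, 8, 8)), c(1, 1, 1))
  expect_error(writeMask(rec2, p), class = "cdseg_no_mask")
})

test_that("an all-zero mask round-trips to all-zero", {
  rec <- volumeRecord(array(rnorm(8 * 8 * 8), dim = c(8, 8, 8)),
                      spacingMm = c(2, 1, 1),
                      mask = array(0, dim = c(8, 8, 8)))
  p <- withr::local_tempfile(fileext = ".nii.gz")
  writeMask(rec, p)
  expect_true(all(voxels(readVolume(p)) == 0))
})

test_that("axial slice extraction is ordered, aligned and invertible", {
  rec <- generatePhantom(tiny_phantom_cfg(c(10L, 12L, 14L)), 3L)
  sl <- extractAxialSlices(rec)
  expect_length(sl$images, 10L)
  expect_identical(dim(sl$images[[1]]), c(12L, 14L))
  expect_length(sl$masks, 10L)
  for (i in c(1L, 5L, 10L)) {
    expect_equal(sl$images[[i]], array(voxels(rec)[i, , ], dim = c(12, 14)))
    expect_equal(sl$masks[[i]], array(volMask(rec)[i, , ], dim = c(12, 14)))
  }
  restack <- aperm(simplify2array(sl$images), c(3, 1, 2))
  expect_identical(restack, voxels(rec))
})

test_that("preprocessSlice windows, normalizes and resizes as configured", {
  m <- matrix(rnorm(32 * 32, sd = 50), 32, 32)
  ident <- preprocessConfig(targetSize = c(32L, 32L),
                            intensityWindow = NULL, normalization = "none")
  expect_equal(preprocessSlice(m, ident), m)

  # windowing clamps before normalization
  win <- preprocessConfig(targetSize = c(32L, 32L),
                          intensityWindow = c(-10, 10),
                          normalization = "none")
  out <- preprocessSlice(m, win)
  expect_true(all(out >= -10 & out <= 10))

  # z-scored output has mean 0 sd 1; constant slices give zeros, not NaN
  zs <- preprocessConfig(targetSize = c(32L, 32L), intensityWindow = NULL,
                         normalization = "zscore")
  z <- preprocessSlice(m, zs)
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(sd(z), 1, tolerance = 1e-10)
  expect_true(all(preprocessSlice(matrix(7, 32, 32), zs) == 0))

  # factor-2 bilinear downsampling equals 2x2 block averaging
  big <- matrix(rnorm(128 * 128), 128, 128)
  down <- preprocessSlice(big, preprocessConfig(
    targetSize = c(64L, 64L), intensityWindow = NULL,
    normalization = "none"))
  blocks <- matrix(0, 64, 64)
  for (i in 1:64) for (j in 1:64)
    blocks[i, j] <- mean(big[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  expect_lt(max(abs(down - blocks)), 1e-5)

  # deterministic: bitwise equal on repeated calls
  expect_identical(preprocessSlice(big, zs), preprocessSlice(big, zs))
})
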