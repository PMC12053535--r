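test_that("NIfTI write/read round-trips data, spacing and label sets", {
  ph <- generatePhantom(shape = c(24, 24, 12), seed = 7)
  f <- tempfile(fileext = ".nii.gz")
  writeVolume(ph$volume, f)
  v2 <- readVolume(f)
  # intensities stored as 32-bit float on disk
  expect_lt(max(abs(volData(v2) - volData(ph$volume))) /
              max(abs(volData(ph$volume))), 1e-6)
  expect_equal(voxelSpacing(v2), voxelSpacing(ph$volume))
  expect_identical(dim(v2), dim(ph$volume))

  fm <- tempfile(fileext = ".nii.gz")
  writeLabelMask(ph$mask, fm)
  m2 <- readLabelMask(fm)
  expect_identical(maskLabels(m2), maskLabels(ph$mask))

  # spacing round-trips to float precision
  v3 <- Volume(array(rnorm(8 * 8 * 4), c(8, 8, 4)), spacing = c(0.5, 0.5, 2))
  f3 <- tempfile(fileext = ".nii.gz")
  writeVolume(v3, f3)
  expect_equal(voxelSpacing(readVolume(f3)), c(0.5, 0.5, 2), tolerance = 1e-6)
})

test_that("read errors are distinct named conditions", {
  expect_error(readVolume(tempfile(fileext = ".nii.gz")),
               class = "gtvMissingFileError")
  # a 4D image (non-singleton 4th axis) is rejected as non-3D
  f4 <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 2, 3))), f4)
  expect_error(readVolume(f4), class = "gtvNon3DImageError")
  # garbage bytes are an unreadable header
  fg <- tempfile(fileext = ".nii")
  writeBin(as.raw(1:64), fg)
  suppressWarnings(expect_error(readVolume(fg), class = "gtvHeaderError"))
})

test_that("resampling follows the shape rule and interpolation contracts", {
  v <- Volume(array(rnorm(64 * 64 * 32), c(64, 64, 32)), spacing = c(1, 1, 2))
  r <- resampleToSpacing(v, c(0.5, 0.5, 2))
  expect_identical(dim(r), c(128L, 128L, 32L))
  expect_equal(voxelSpacing(r), c(0.5, 0.5, 2))

  # identity resample leaves shape and data unchanged
  same <- resampleToSpacing(v, c(1, 1, 2))
  expect_identical(dim(same), dim(v))
  expect_lt(max(abs(volData(same) - volData(v))), 1e-10)

  # linear interpolation never exceeds the input range
  fine <- resampleToSpacing(v, c(0.7, 1.3, 1.1))
  expect_gte(min(volData(fine)), min(volData(v)))
  expect_lte(max(volData(fine)), max(volData(v)))

  # nearest-neighbor preserves the label set
  lab <- array(0L, c(16, 16, 8)); lab[4:9, 4:9, 3:5] <- 2L
  m <- LabelMask(lab, spacing = c(1, 1, 2))
  mr <- resampleToSpacing(m, c(0.4, 0.7, 1.1))
  expect_true(all(unique(as.vector(maskLabels(mr))) %in% c(0L, 2L)))

  expect_error(resampleToSpacing(v, c(0, 1, 1)), class = "gtvSpacingError")
})

test_that("restoreToOrigin reproduces the source grid exactly", {
  ph <- generatePhantom(shape = c(32, 32, 16), seed = 3)
  f <- tempfile(fileext = ".nii.gz")
  writeLabelMask(ph$mask, f)
  m <- readLabelMask(f)
  away <- resampleToSpacing(m, c(0.5, 0.5, 1))
  back <- restoreToOrigin(away)
  expect_identical(dim(back), c(32L, 32L, 16L))
  expect_equal(voxelSpacing(back), voxelSpacing(m))

  # already on the original grid: returned unchanged
  expect_identical(maskLabels(restoreToOrigin(m)), maskLabels(m))

  # missing origin metadata is an error
  bare <- LabelMask(maskLabels(ph$mask), originMeta = list())
  expect_error(restoreToOrigin(bare), class = "gtvMissingOriginError")
})

test_that("a sphere survives a 2x-finer round trip at >= 99% voxel agreement", {
  shape <- c(40, 40, 20)
  ax <- lapply(1:3, function(a) seq_len(shape[a]) - 1)
  r2 <- outer(outer((ax[[1]] - 19.5)^2 / 144, (ax[[2]] - 19.5)^2 / 144, "+"),
              (ax[[3]] - 9.5)^2 / 36, "+")
  lab <- array(0L, shape); lab[r2 <= 1] <- 1L
  f <- tempfile(fileext = ".nii.gz")
  writeLabelMask(LabelMask(lab, spacing = c(1, 1, 2)), f)
  m <- readLabelMask(f)
  fine <- resampleToSpacing(m, c(0.5, 0.5, 1))
  back <- restoreToOrigin(fine)
  agreement <- mean(maskLabels(back) == lab)
  expect_gte(agreement, 0.99)
})
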