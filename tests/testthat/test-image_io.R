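test_that("to_hu applies the scanner rescale element-wise", {
  vox <- array(c(0L, 1024L, 100L, 7L), c(1, 2, 2))
  v <- ctenhance:::new_raw_volume(vox, 1, -1024, c(1, 1, 1))
  hu <- to_hu(v, 1)
  expect_equal(hu[1, 1], -1024)
  expect_equal(hu[2, 1], 0)

  v2 <- ctenhance:::new_raw_volume(array(100L, c(1, 1, 1)), 2, -50, c(1, 1, 1))
  expect_equal(to_hu(v2, 1)[1, 1], 150)

  expect_error(to_hu(v, 0), "out of range")
  expect_error(to_hu(v, 2), "out of range")
})

test_that("to_hu is exactly affine in the stored values", {
  set.seed(4)
  stored <- array(sample(-1024:3071, 3 * 8 * 8, replace = TRUE), c(3, 8, 8))
  v <- ctenhance:::new_raw_volume(stored, 1.5, -1000, c(1, 1, 1))
  for (s in 1:3)
    expect_identical(to_hu(v, s), stored[s, , ] * 1.5 - 1000)
})

test_that("normalize_minmax maps [min,max] to [0,255], half-up, constants to zero", {
  img <- matrix(c(-1024, 3071, 0, 100), 2, 2)
  out <- normalize_minmax(img)
  expect_identical(out[img == -1024], 0L)
  expect_identical(out[img == 3071], 255L)

  expect_true(all(normalize_minmax(matrix(55, 4, 4)) == 0L))

  mid <- normalize_minmax(matrix(c(0, 510, 255, 255), 2, 2))
  expect_identical(mid[1, 2], 128L)  # 127.5 rounds half-up

  set.seed(1)
  for (i in 1:20) {
    m <- matrix(rnorm(64, sd = 500), 8, 8)
    o <- normalize_minmax(m)
    expect_identical(range(o), c(0L, 255L))
  }
})

test_that("PNG round-trip of byte images and masks is bit-exact", {
  set.seed(2)
  img <- random_byte_image(17, 23)
  p <- file.path(withr::local_tempdir(), "a.png")
  write_png(img, p)
  expect_identical(read_png_byte(p), img)

  mask <- random_mask(17, 23)
  pm <- file.path(dirname(p), "m.png")
  write_mask(mask, pm)
  expect_identical(read_mask(pm), mask)
})

test_that("PNG masks with intermediate gray levels are rejected", {
  p <- file.path(withr::local_tempdir(), "bad.png")
  png::writePNG(matrix(7 / 255, 4, 4), p)
  expect_error(read_mask(p), "other than \\{0, 255\\}")
})

test_that("NIfTI volumes and masks round-trip through read_volume/read_mask", {
  td <- withr::local_tempdir()
  set.seed(3)
  arr <- array(sample(-1024:2000, 64 * 64 * 3, replace = TRUE), c(64, 64, 3))
  storage.mode(arr) <- "integer"
  p <- file.path(td, "vol.nii.gz")
  attr(arr, "pixdim") <- c(0.8, 0.8, 5)
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "int16"), p)
  v <- read_volume(p)
  expect_s3_class(v, "raw_volume")
  expect_identical(dim(v$voxels), c(3L, 64L, 64L))
  expect_equal(v$spacing, c(5, 0.8, 0.8))
  expect_identical(v$voxels[2, , ], arr[, , 2])

  mask <- random_mask(12, 9)
  pm <- file.path(td, "mask.nii.gz")
  write_mask(mask, pm)
  expect_identical(read_mask(pm), mask)

  bad <- file.path(td, "bad.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(matrix(c(0L, 3L, 1L, 0L), 2, 2)), bad)
  expect_error(read_mask(bad), "other than \\{0, 1\\}")
})

test_that("read_volume rejects missing and unreadable inputs", {
  expect_error(read_volume(file.path(tempdir(), "nope.nii")), "not found")
  empty <- withr::local_tempdir()
  writeLines("not dicom at all", file.path(empty, "junk.txt"))
  expect_error(read_volume(empty), "no readable DICOM")
})

test_that("DICOM series round-trip: values, rescale, spacing, ordering", {
  td <- withr::local_tempdir()
  set.seed(5)
  vox <- array(sample(-1000:2000, 2 * 64 * 64, replace = TRUE), c(2, 64, 64))
  write_dicom_series(vox, td, rescale_slope = 1, rescale_intercept = -1024,
                     spacing = c(2.5, 0.7, 0.7))
  v <- read_volume(td)
  expect_identical(dim(v$voxels), c(2L, 64L, 64L))
  expect_true(all(v$voxels == vox))
  expect_equal(v$rescale_slope, 1)
  expect_equal(v$rescale_intercept, -1024)
  expect_equal(v$spacing, c(2.5, 0.7, 0.7), tolerance = 1e-12)
})

test_that("DICOM slices are ordered by position regardless of filename", {
  td <- withr::local_tempdir()
  vox <- array(0L, c(3, 8, 8))
  for (s in 1:3) vox[s, , ] <- s * 100L
  write_dicom_series(vox, td, spacing = c(1, 1, 1))
  files <- list.files(td, full.names = TRUE)
  # shuffle filenames so lexical order disagrees with spatial order
  tmp <- file.path(td, "zz_first.dcm")
  file.rename(files[3], tmp)
  v <- read_volume(td)
  expect_equal(v$voxels[, 1, 1], c(100L, 200L, 300L))
})

test_that("a directory mixing two series is rejected", {
  td <- withr::local_tempdir()
  vox <- array(1L, c(1, 8, 8))
  write_dicom_series(vox, td, series_uid = "2.25.111")
  f1 <- list.files(td, full.names = TRUE)
  write_dicom_series(vox, file.path(td, "b"), series_uid = "2.25.222")
  file.copy(list.files(file.path(td, "b"), full.names = TRUE),
            file.path(td, "other.dcm"))
  unlink(file.path(td, "b"), recursive = TRUE)
  expect_error(read_volume(td), "multiple DICOM series")
})
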