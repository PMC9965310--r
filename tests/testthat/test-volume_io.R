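# Volume I/O: format round trips, geometry fidelity, ROI crop and
# isotropic resampling.

test_that("NRRD round trips are voxelwise identical", {
  set.seed(1)
  v <- volume_image(array(rnorm(1000), c(10, 10, 10)),
                    c(0.08, 0.08, 0.08), c(1, -2, 3))
  for (enc in c("raw", "gzip")) {
    f <- withr::local_tempfile(fileext = ".nrrd")
    write_nrrd(v, f, encoding = enc)
    v2 <- read_nrrd(f)
    expect_identical(v2$data, v$data)
    expect_equal(v2$spacing, v$spacing)
    expect_equal(v2$origin, v$origin)
    expect_equal(v2$orientation, v$orientation)
  }
})

test_that("NIfTI round trips preserve grid, intensities and geometry", {
  set.seed(2)
  v <- volume_image(array(rnorm(720), c(8, 9, 10)), c(0.1, 0.2, 0.3),
                    c(-1, 5, 2))
  for (ext in c(".nii", ".nii.gz")) {
    f <- withr::local_tempfile(fileext = ext)
    write_nifti(v, f)
    v2 <- read_nifti(f)
    expect_equal(v2$data, v$data, tolerance = 1e-12)
    # sform rows are float32 in the file
    expect_lt(max(abs(v2$origin - v$origin)), 1e-5)
    expect_lt(max(abs(v2$spacing - v$spacing)), 1e-6)
    expect_lt(max(abs(v2$orientation - diag(3))), 1e-6)
  }
})

test_that("DICOM series round trips report anisotropic spacing faithfully", {
  set.seed(3)
  v <- volume_image(array(round(rnorm(8 * 6 * 2, 0, 300)), c(8, 6, 2)),
                    c(0.08, 0.08, 0.13), c(4, -3, 7))
  d <- withr::local_tempdir()
  write_dicom_series(v, d)
  v2 <- read_dicom_series(d)
  expect_equal(dim(v2$data), dim(v$data))
  expect_equal(v2$spacing, v$spacing, tolerance = 1e-9)
  expect_equal(v2$origin, v$origin, tolerance = 1e-9)
  expect_equal(v2$data, v$data, tolerance = 1e-9)
})

test_that("DICOM rescale slope/intercept reproduces non-integer data", {
  set.seed(4)
  v <- volume_image(array(rnorm(125), c(5, 5, 5)), c(0.1, 0.1, 0.1))
  d <- withr::local_tempdir()
  write_dicom_series(v, d)
  v2 <- read_dicom_series(d)
  rng <- diff(range(v$data))
  expect_lt(max(abs(v2$data - v$data)), rng / 65000 * 2)
})

test_that("inconsistent DICOM slice spacing is rejected with file names", {
  v <- volume_image(array(0, c(4, 4, 3)), c(0.1, 0.1, 0.1))
  d <- withr::local_tempdir()
  write_dicom_series(v, d)
  # an extra slice at a non-uniform position
  stray <- volume_image(array(0, c(4, 4, 1)), c(0.1, 0.1, 0.1),
                        c(0, 0, 0.45))
  d2 <- withr::local_tempdir()
  write_dicom_series(stray, d2)
  file.copy(file.path(d2, "slice_0001.dcm"),
            file.path(d, "slice_0004.dcm"))
  expect_error(read_dicom_series(d), "inconsistent.*slice_0004",
               ignore.case = TRUE)
})

test_that("read_volume dispatches and rejects missing files", {
  expect_error(read_volume("/no/such/file.nrrd"), "not found")
  ph <- pit_phantom()
  f <- withr::local_tempfile(fileext = ".nrrd")
  write_volume(ph$volume, f)
  v2 <- read_volume(f)
  expect_identical(v2$data, ph$volume$data)
})

test_that("crop_roi retains exactly the voxel centers in the closed cube", {
  v <- make_vol(array(seq_len(1e6) + 0, c(100, 100, 100)),
                origin = c(0.05, 0.05, 0.05))
  # centers at 0.05 .. 9.95; cube [2.5, 7.5] -> 50 per axis
  cr <- crop_roi(v, region_of_interest(c(5, 5, 5), 5))
  expect_equal(dim(cr$data), c(50L, 50L, 50L))
  # cube boundary exactly on centers -> 51 (closed cube)
  cr2 <- crop_roi(v, region_of_interest(c(5.05, 5.05, 5.05), 5))
  expect_equal(dim(cr2$data), c(51L, 51L, 51L))
})

test_that("crop_roi clamps with a warning and preserves world coordinates", {
  set.seed(5)
  v <- make_vol(array(rnorm(27e3), c(30, 30, 30)))
  expect_warning(full <- crop_roi(v, region_of_interest(c(1.5, 1.5, 1.5),
                                                        50)),
                 "clamped")
  expect_identical(full$data, v$data)
  cr <- crop_roi(v, region_of_interest(c(1.5, 1.5, 1.5), 1))
  # pick a voxel and check its world position and value are unchanged
  w_before <- index_to_world(v, cbind(14, 14, 14))
  idx_after <- world_to_index(cr, w_before)
  val <- cr$data[matrix(round(idx_after) + 1, 1)]
  expect_identical(val, v$data[15, 15, 15])
  expect_world_equal(index_to_world(cr, round(idx_after)), w_before)
  # idempotence
  cr2 <- crop_roi(cr, region_of_interest(c(1.5, 1.5, 1.5), 1))
  expect_identical(cr2$data, cr$data)
  expect_equal(cr2$origin, cr$origin)
  # fully outside -> geometry error
  expect_error(crop_roi(v, region_of_interest(c(50, 50, 50), 1)),
               "outside")
})

test_that("resample_isotropic activates exactly above the target spacing", {
  v1 <- volume_image(array(1:27 + 0, c(3, 3, 3)), c(0.08, 0.08, 0.08))
  expect_identical(resample_isotropic(v1, 0.1), v1)
  v2 <- volume_image(array(rnorm(27), c(3, 3, 3)), c(0.1, 0.1, 0.1))
  expect_identical(resample_isotropic(v2, 0.1), v2)
  v3 <- volume_image(array(rnorm(16^3), c(16, 16, 16)), c(0.3, 0.3, 0.3))
  r3 <- resample_isotropic(v3, 0.1)
  expect_equal(r3$spacing, c(0.1, 0.1, 0.1))
  expect_equal(dim(r3$data), c(48L, 48L, 48L))
  expect_error(resample_isotropic(v3, NaN), "finite")
})

test_that("resampling a constant volume preserves the constant exactly", {
  v <- volume_image(array(42, c(8, 8, 8)), c(0.25, 0.25, 0.25))
  r <- resample_isotropic(v, 0.1)
  expect_true(all(r$data == 42))
  # never extrapolates: values stay within the input range
  set.seed(6)
  v2 <- volume_image(array(runif(512), c(8, 8, 8)), c(0.3, 0.3, 0.3))
  r2 <- resample_isotropic(v2, 0.1)
  expect_gte(min(r2$data), min(v2$data))
  expect_lte(max(r2$data), max(v2$data))
})
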