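test_that("NIfTI write/read round-trips data, spacing and origin exactly", {
  set.seed(11)
  g <- voxel_grid(array(rnorm(4 * 5 * 6), c(4, 5, 6)),
                  spacing = c(1, 1, 3), origin = c(-10, 5, 2.5), role = "CT")
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(g, f)
  g2 <- read_volume(f, role = "CT")
  expect_identical(g2$data, g$data)
  expect_equal(g2$spacing, g$spacing)
  expect_equal(g2$origin, g$origin)
})

test_that("boolean masks are stored as 0/1 integer volumes", {
  m <- array(FALSE, c(3, 4, 5)); m[2, 2, 2] <- TRUE; m[3, 4, 5] <- TRUE
  g <- voxel_grid(m, spacing = c(2, 2, 2), role = "mask")
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(g, f)
  img <- RNifti::readNifti(f)
  vals <- as.vector(as.array(img))
  expect_true(all(vals %in% c(0, 1)))
  expect_true(RNifti::niftiHeader(img)$datatype %in% c(2L, 4L, 8L, 512L))  # integer storage
  back <- read_volume(f, role = "mask")
  expect_identical(back$data, m)
})

test_that("unreadable and non-3-D inputs are rejected with a clear message", {
  expect_error(read_volume(file.path(tempdir(), "nope.nii.gz")), "not found")
  junk <- withr::local_tempfile(fileext = ".nii")
  writeLines("not a nifti", junk)
  suppressWarnings(expect_error(read_volume(junk), "NIfTI"))
  f2 <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(matrix(0, 4, 4)), f2)
  expect_error(read_volume(f2), "3-D")
})

test_that("voxel_grid enforces its invariants", {
  expect_error(voxel_grid(array(0, c(2, 2)), c(1, 1, 1)), "3-D")
  expect_error(voxel_grid(array(0, c(2, 2, 2)), c(1, -1, 1)), "positive")
  expect_error(voxel_grid(array(-1, c(2, 2, 2)), role = "PET"), "non-negative")
})

test_that("compute_suv matches the body-weight contract", {
  pet <- voxel_grid(array(5000, c(3, 3, 3)), role = "PET")
  cal <- suv_calibration(370, 60, 74)
  # 370 MBq / 74 kg = 5000 Bq/g, so uniform 5000 Bq/ml gives SUV 1
  suv <- compute_suv(pet, cal, decay_correct = FALSE)
  expect_equal(suv$data, array(1, c(3, 3, 3)))
  # inversely linear in dose
  suv2 <- compute_suv(pet, suv_calibration(740, 60, 74), decay_correct = FALSE)
  expect_equal(suv2$data, suv$data / 2)
  # homogeneous of degree 1 in activity
  pet3 <- voxel_grid(3 * pet$data, role = "PET")
  expect_equal(compute_suv(pet3, cal, decay_correct = FALSE)$data, 3 * suv$data)
})

test_that("decay correction scales SUV by 2^(t / half-life)", {
  pet <- voxel_grid(array(5000, c(2, 2, 2)), role = "PET")
  cal <- suv_calibration(370, 109.77, 74)  # exactly one F-18 half-life
  un <- compute_suv(pet, cal, decay_correct = FALSE)
  co <- compute_suv(pet, cal, decay_correct = TRUE)
  expect_equal(co$data, 2 * un$data)
})

test_that("invalid calibrations are rejected naming the field", {
  expect_error(suv_calibration(0, 60, 74), "injected_activity")
  expect_error(suv_calibration(370, 60, -1), "weight")
})

test_that("resampling onto an identical geometry is the identity", {
  set.seed(4)
  g <- voxel_grid(array(rnorm(60), c(3, 4, 5)), spacing = c(2, 2, 2))
  ref <- voxel_grid(array(0, c(3, 4, 5)), spacing = c(2, 2, 2))
  for (interp in c("trilinear", "nearest"))
    expect_equal(resample_to_grid(g, ref, interp)$data, g$data)
})

test_that("a constant volume stays constant under either interpolation", {
  g <- voxel_grid(array(7, c(8, 8, 8)), spacing = c(2, 2, 2))
  ref <- voxel_grid(array(0, c(4, 4, 4)), spacing = c(3, 3, 3),
                    origin = c(1, 1, 1))
  for (interp in c("trilinear", "nearest"))
    expect_equal(unique(as.vector(resample_to_grid(g, ref, interp)$data)), 7)
})

test_that("trilinear downsampling of a linear ramp is exact", {
  d <- c(16, 16, 16)
  ramp <- function(x, y, z) 2 * x + 3 * y - z + 5  # linear in physical mm
  co <- lapply(1:3, function(ax) (seq_len(d[ax]) - 1) * 1)
  vol <- array(0, d)
  for (k in seq_len(d[3])) vol[, , k] <-
      outer(co[[1]], co[[2]], function(x, y) ramp(x, y, co[[3]][k]))
  g <- voxel_grid(vol, spacing = c(1, 1, 1))
  ref <- voxel_grid(array(0, c(7, 7, 7)), spacing = c(2, 2, 2),
                    origin = c(0.5, 0.5, 0.5))
  out <- resample_to_grid(g, ref, "trilinear")
  expected <- array(0, c(7, 7, 7))
  rc <- lapply(1:3, function(ax) 0.5 + (0:6) * 2)
  for (k in 1:7) expected[, , k] <-
      outer(rc[[1]], rc[[2]], function(x, y) ramp(x, y, rc[[3]][k]))
  expect_lt(max(abs(out$data - expected)), 1e-6)
})

test_that("disjoint grids are rejected; masks stay logical under nearest", {
  a <- voxel_grid(array(1, c(4, 4, 4)), origin = c(0, 0, 0))
  b <- voxel_grid(array(1, c(4, 4, 4)), origin = c(100, 100, 100))
  expect_error(resample_to_grid(a, b), "overlap")
  m <- voxel_grid(array(c(TRUE, FALSE), c(4, 4, 4)), spacing = c(2, 2, 2),
                  role = "mask")
  ref <- voxel_grid(array(0, c(8, 8, 8)), spacing = c(1, 1, 1))
  out <- resample_to_grid(m, ref, "nearest")
  expect_type(out$data, "logical")
})

test_that("a phantom survives a NIfTI round trip with identical segmentation", {
  ph <- generate_phantom(small_phantom_spec(seed = 3))
  dir <- withr::local_tempdir()
  write_volume(ph$ct, file.path(dir, "ct.nii.gz"))
  ct2 <- read_volume(file.path(dir, "ct.nii.gz"), role = "CT")
  tr <- sample_training_voxels(ph$ct, ph$truth_cortical, ph$truth_trabecular,
                               400, seed = 5)
  segment <- function(ct) {
    bone <- extract_bone_mask(ct, 100, 3)
    classify_compartments(posterior_map(train_lda(tr), ct, bone))
  }
  expect_identical(segment(ct2), segment(ph$ct))
})
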