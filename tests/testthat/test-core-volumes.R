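test_that("labelmap NIfTI round trip preserves values and spacing", {
  lm <- labelmap3d(array(sample(0:17, 1000, replace = TRUE), c(10, 10, 10)),
                   spacing = c(1, 1, 1.5), semantics = "level")
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_nifti(lm, f)
  r <- read_labelmap(f, "level")
  expect_identical(r$values, lm$values)
  expect_equal(r$spacing, lm$spacing)
})

test_that("float-stored integral values are accepted, fractional rejected", {
  f <- withr::local_tempfile(fileext = ".nii")
  RNifti::writeNifti(RNifti::asNifti(array(c(0, 1, 2, 3, 0, 3, 1, 2), c(2, 2, 2))),
                     f, datatype = "float")
  r <- read_labelmap(f, "instance")
  expect_type(r$values, "integer")
  expect_equal(as.vector(r$values), c(0L, 1L, 2L, 3L, 0L, 3L, 1L, 2L))

  f2 <- withr::local_tempfile(fileext = ".nii")
  RNifti::writeNifti(RNifti::asNifti(array(c(0, 0.5, 1, 1, 0, 0, 1, 1), c(2, 2, 2))),
                     f2, datatype = "float")
  expect_error(read_labelmap(f2, "binary"), "non-integer")
  expect_error(read_labelmap(tempfile(), "binary"), "not found")
})

test_that("resampling follows the ceil(shape * spacing / target) contract", {
  lm <- labelmap3d(array(0L, c(100, 100, 50)), spacing = c(0.8, 0.8, 2.0),
                   semantics = "binary")
  r <- resample_isotropic(lm, 1)
  expect_equal(dim(r$values), c(80L, 80L, 100L))
  expect_equal(r$spacing, c(1, 1, 1))

  # identity when already at target spacing
  lm1 <- labelmap3d(array(sample(0:1, 64, TRUE), c(4, 4, 4)),
                    semantics = "binary")
  expect_identical(resample_isotropic(lm1, 1)$values, lm1$values)
  expect_error(resample_isotropic(lm1, -1), "positive")
})

test_that("nearest-neighbor resampling never blends label values", {
  lm <- labelmap3d(array(sample(c(0L, 3L), 20 * 20 * 10, TRUE), c(20, 20, 10)),
                   spacing = c(0.7, 1.3, 2.1), semantics = "instance")
  r <- resample_isotropic(lm, 1)
  expect_true(all(unique(as.vector(r$values)) %in% c(0L, 3L)))
  # resampling back preserves the label value set
  back <- resample_isotropic(r, 0.7)
  expect_true(all(unique(as.vector(back$values)) %in% c(0L, 3L)))
  # physical extent preserved within one voxel per axis
  expect_true(all(abs(dim(r$values) * 1 - dim(lm$values) * lm$spacing) <= 1))
})

test_that("intensity resampling interpolates a linear field exactly", {
  # trilinear interpolation reproduces an affine intensity ramp
  d <- c(9, 9, 9)
  ramp <- array(0, d)
  for (k in 1:9) ramp[, , k] <- outer(1:9, 1:9, function(i, j) 2 * i + 3 * j) + 5 * k
  v <- volume3d(ramp, spacing = c(2, 2, 2))
  r <- resample_isotropic(v, 1)
  # interior check against the analytic field at 1 mm positions
  expect_equal(r$values[3, 5, 7],
               2 * (1 + 2 / 2) + 3 * (1 + 4 / 2) + 5 * (1 + 6 / 2),
               tolerance = 1e-12)
})

test_that("intensity normalization maps the window onto [-0.5, 1.5] with clipping", {
  v <- volume3d(array(c(-2000, -1000, 0, 1000, 2000, 500, -250, 42), c(2, 2, 2)))
  nv <- normalize_intensity(v)
  expect_equal(nv$values[2, 1, 1], -0.5)  # window_low
  expect_equal(nv$values[2, 2, 1], 1.5)   # window_high
  expect_equal(nv$values[1, 2, 1], 0.5)   # midpoint
  expect_equal(nv$values[1, 1, 1], -0.5)  # clipped below
  expect_equal(nv$values[1, 1, 2], 1.5)   # clipped above
  expect_true(all(nv$values >= -0.5 & nv$values <= 1.5))
  # monotone non-decreasing
  x <- sort(stats::runif(50, -1500, 1500))
  vx <- normalize_intensity(volume3d(array(x, c(50, 1, 1))))
  expect_true(all(diff(vx$values[, 1, 1]) >= 0))
  # idempotent when the window equals the output range
  again <- normalize_intensity(nv, -0.5, 1.5)
  expect_equal(again$values, nv$values, tolerance = 1e-12)
  expect_error(normalize_intensity(v, 10, 10), "window")
})

test_that("container invariants are enforced", {
  expect_error(volume3d(array(0, c(2, 2)), c(1, 1, 1)), "3-D")
  expect_error(volume3d(array(0, c(2, 2, 2)), c(1, -1, 1)), "positive")
  expect_error(labelmap3d(array(0.5, c(2, 2, 2))), "integer")
  expect_error(labelmap3d(array(2L, c(2, 2, 2)), semantics = "binary"), "0 or 1")
  expect_error(labelmap3d(array(18L, c(2, 2, 2)), semantics = "level"), "0..17")
})

test_that("level code table is the fixed T1..L5 ordering", {
  expect_equal(level_code("T1"), 1L)
  expect_equal(level_code("T12"), 12L)
  expect_equal(level_code("L1"), 13L)
  expect_equal(level_code("L5"), 17L)
  expect_equal(level_name(c(1, 12, 13, 17)), c("T1", "T12", "L1", "L5"))
  expect_error(level_code("C3"), "Unknown")
  expect_error(level_name(18), "1..17")
})
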