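make_binary <- function(arr, spacing = c(1, 1, 1)) {
  labelmap3d(array(as.integer(arr > 0), dim(arr)), spacing = spacing,
             semantics = "binary")
}

test_that("connected components match counts and connectivity semantics", {
  # empty map
  empty <- make_binary(array(0L, c(5, 5, 5)))
  expect_equal(nrow(extract_components(empty)$table), 0L)

  # two disjoint cubes with exact voxel counts
  m <- array(0L, c(12, 12, 12))
  m[2:4, 2:4, 2:4] <- 1L      # 27 voxels
  m[7:10, 7:10, 8:11] <- 1L   # 64 voxels
  cc <- extract_components(make_binary(m))
  expect_equal(nrow(cc$table), 2L)
  expect_setequal(cc$table$n_voxels, c(27L, 64L))
  # ids ordered cranial (higher axis-3 position) first
  expect_equal(cc$table$n_voxels[1], 64L)

  # diagonal corner contact: one component at 26-connectivity, two at 6
  m2 <- array(0L, c(6, 6, 6))
  m2[1:2, 1:2, 1:2] <- 1L
  m2[3:4, 3:4, 3:4] <- 1L
  expect_equal(nrow(extract_components(make_binary(m2), 26)$table), 1L)
  expect_equal(nrow(extract_components(make_binary(m2), 6)$table), 2L)
  expect_error(extract_components(labelmap3d(array(2L, c(2, 2, 2)),
                                             semantics = "instance")),
               "binary")
})

test_that("component labeling agrees with brute-force flood fill on small grids", {
  for (seed in 1:6) {
    d <- c(sample(8:20, 1), sample(8:20, 1), sample(8:20, 1))
    m <- random_mask(d, 0.35, seed = 100 + seed)
    for (conn in c(6, 26)) {
      got <- extract_components(make_binary(m), conn)
      want <- brute_components(m, conn)
      expect_equal(nrow(got$table), max(want))
      # identical partitions up to label renaming
      pairs <- unique(cbind(as.vector(got$labels)[m], as.vector(want)[m]))
      expect_equal(nrow(pairs), max(want))
    }
  }
})

test_that("candidate filtering keeps clean vertebrae and removes islands", {
  ph <- generate_phantom(phantom_spec(n_vertebrae = 5, seed = 31))
  pred <- corrupt_prediction(ph$instances, ph$levels, corruption_spec(seed = 32))

  # clean phantom: everything retained
  clean <- refine_binary(pred$binary)
  expect_equal(nrow(clean$table), 5L)
  expect_equal(sum(clean$labels > 0L), sum(pred$binary$values > 0L))

  # a 50-voxel island far lateral to the spine axis is removed
  arr <- pred$binary$values
  arr[2:6, 2:6, 80:81] <- 1L
  withisland <- refine_binary(make_binary(arr))
  expect_equal(nrow(withisland$table), 5L)
  expect_gt(sum(withisland$log$action == "remove_size"), 0L)
})

test_that("edge-contacting half-vertebrae survive via the exemption", {
  ph <- generate_phantom(phantom_spec(n_vertebrae = 5, partial_at_edges = TRUE,
                                      seed = 33))
  # truncated body is below the plain minimum volume
  expect_lt(ph$levels$n_voxels[1], 5000)
  pred <- corrupt_prediction(ph$instances, ph$levels, corruption_spec(seed = 34))
  ref <- refine_binary(pred$binary)
  expect_equal(nrow(ref$table), 5L)
  expect_true(any(ref$table$edge_contact))
})

test_that("watershed split is a voxel-exact partition restoring the pair", {
  ph <- generate_phantom(phantom_spec(n_vertebrae = 5, seed = 35))
  pred <- corrupt_prediction(ph$instances, ph$levels,
                             corruption_spec(fuse_pairs = list(c(3, 4)), seed = 36))
  before <- extract_components(pred$binary)
  expect_equal(nrow(before$table), 4L)
  after <- split_fused(before)
  expect_equal(nrow(after$table), 5L)
  # exact partition: identical foreground, no voxel lost or gained
  expect_identical(after$labels > 0L, before$labels > 0L)
  # centroids ordered craniocaudally
  expect_true(all(diff(after$table$centroid_z_mm) < 0))
})

test_that("a chain of three fused bodies splits into three ordered instances", {
  ph <- generate_phantom(phantom_spec(n_vertebrae = 5, seed = 37))
  pred <- corrupt_prediction(ph$instances, ph$levels,
                             corruption_spec(fuse_pairs = list(c(2, 3), c(3, 4)),
                                             seed = 38))
  expect_equal(nrow(extract_components(pred$binary)$table), 3L)
  ref <- refine_binary(pred$binary)
  expect_equal(nrow(ref$table), 5L)
  expect_true(all(diff(ref$table$centroid_z_mm) < 0))
})

test_that("refinement never adds foreground and is idempotent", {
  ph <- generate_phantom(phantom_spec(n_vertebrae = 5, seed = 39))
  pred <- corrupt_prediction(ph$instances, ph$levels,
                             corruption_spec(fuse_pairs = list(c(1, 2)),
                                             n_islands = 2, seed = 40))
  ref <- refine_binary(pred$binary)
  expect_true(all(pred$binary$values[ref$labels > 0L] == 1L))

  refined_binary <- make_binary(ref$labels)
  again <- refine_binary(refined_binary)
  # identical instance partition (ids included, both craniocaudally ordered)
  expect_identical(again$labels, ref$labels)
})

test_that("an unsplittable suspect passes through with a logged warning", {
  # an elongated ellipsoid has one interior distance peak: suspect height
  # (60 mm > 1.6 x 28 mm) but nothing to split
  d <- c(45, 45, 70)
  ctr <- c(23, 23, 35)
  g <- arrayInd(seq_len(prod(d)), d)
  inside <- ((g[, 1] - ctr[1]) / 20)^2 + ((g[, 2] - ctr[2]) / 20)^2 +
    ((g[, 3] - ctr[3]) / 30)^2 <= 1
  m <- array(as.integer(inside), d)
  iseg <- extract_components(make_binary(m))
  expect_warning(out <- split_fused(iseg), "single distance")
  expect_equal(nrow(out$table), 1L)
  expect_identical(out$labels, iseg$labels)
  expect_true(any(out$log$action == "unsplittable_suspect"))
})
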