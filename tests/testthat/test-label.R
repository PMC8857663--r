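test_that("level consensus returns the modal level and exact fraction", {
  lp <- labelmap3d(array(13L, c(4, 4, 4)), semantics = "level")
  cs <- level_consensus(array(TRUE, c(4, 4, 4)), lp)
  expect_equal(cs$level_name, "L1")
  expect_equal(cs$confidence, 1.0)

  # 60/40 split
  v <- array(0L, c(10, 10, 10))
  v[, , 1:10] <- 8L
  v[1:6, , ] <- 7L   # 600 voxels T7, 400 voxels T8
  lp2 <- labelmap3d(v, semantics = "level")
  cs2 <- level_consensus(array(TRUE, c(10, 10, 10)), lp2)
  expect_equal(cs2$level_name, "T7")
  expect_equal(cs2$confidence, 0.60)

  # no overlap
  cs3 <- level_consensus(array(TRUE, c(2, 2, 2)),
                         labelmap3d(array(0L, c(2, 2, 2)), semantics = "level"))
  expect_true(is.na(cs3$level_code))
  expect_error(level_consensus(array(TRUE, c(3, 3, 3)), lp), "misaligned")
})

test_that("anchor status flips exactly at the 95% consensus threshold", {
  at <- cube_inputs(950)    # consensus 0.950: anchored, labeled T7
  ls <- sequential_approach(at$binary, at$level)
  expect_true(ls$table$anchor)
  expect_equal(ls$table$level_name, "T7")
  expect_equal(ls$table$confidence, 0.95)

  below <- cube_inputs(949)  # consensus 0.949: no anchor anywhere -> loud failure
  expect_error(sequential_approach(below$binary, below$level), "No anchor")
})

test_that("a single anchor propagates by craniocaudal position counting", {
  ph <- generate_phantom(phantom_spec(n_vertebrae = 5, first_level = "T6",
                                      seed = 41))
  pred <- corrupt_prediction(ph$instances, ph$levels, corruption_spec(seed = 42))
  iseg <- refine_binary(pred$binary)
  anchors <- tibble::tibble(
    instance_id = 1:5,
    level_code = c(NA, NA, 8L, NA, NA),  # only the middle instance anchors T8
    confidence = c(NA, NA, 1, NA, NA),
    anchor = c(FALSE, FALSE, TRUE, FALSE, FALSE)
  )
  out <- propagate_labels(iseg, anchors)
  expect_equal(out$table$level_name, c("T6", "T7", "T8", "T9", "T10"))

  # all-anchor consecutive input is returned unchanged
  full <- tibble::tibble(instance_id = 1:5, level_code = 6:10,
                         confidence = rep(1, 5), anchor = rep(TRUE, 5))
  expect_equal(propagate_labels(iseg, full)$table$level_code, 6:10)

  # no anchors at all fails loudly
  none <- dplyr::mutate(full, anchor = FALSE)
  expect_error(propagate_labels(iseg, none), "No anchor")

  # propagation past T1 errors
  low <- tibble::tibble(instance_id = 1:5, level_code = c(NA, NA, NA, NA, 2L),
                        confidence = c(NA, NA, NA, NA, 1),
                        anchor = c(rep(FALSE, 4), TRUE))
  expect_error(propagate_labels(iseg, low), "past T1 or L5")
})

test_that("conflicting anchors resolve by confidence, ties to the superior", {
  ph <- generate_phantom(phantom_spec(n_vertebrae = 5, first_level = "T6",
                                      seed = 43))
  pred <- corrupt_prediction(ph$instances, ph$levels, corruption_spec(seed = 44))
  iseg <- refine_binary(pred$binary)
  # anchors at both ends disagree by one level; instance 3 is equidistant
  anchors <- tibble::tibble(
    instance_id = 1:5,
    level_code = c(6L, NA, NA, NA, 11L),  # T6 ... T11 (one too caudal)
    confidence = c(0.99, NA, NA, NA, 0.96),
    anchor = c(TRUE, FALSE, FALSE, FALSE, TRUE)
  )
  out <- propagate_labels(iseg, anchors)
  # middle instance follows the higher-confidence (superior) anchor
  expect_equal(out$table$level_code[3], 8L)
  expect_true(any(out$log$action == "anchor_conflict"))
})

test_that("both approaches recover clean phantoms identically", {
  ph <- generate_phantom(phantom_spec(n_vertebrae = 6, first_level = "T11",
                                      seed = 45))
  pred <- corrupt_prediction(ph$instances, ph$levels, corruption_spec(seed = 46))
  s <- sequential_approach(pred$binary, pred$level)
  c <- combined_approach(pred$level)
  expect_equal(s$table$level_name, ph$levels$level_name)
  expect_equal(c$table$level_name, ph$levels$level_name)
  expect_identical(s$labels, c$labels)  # same refined geometry
  expect_true(all(s$table$anchor))
  # voxelwise output labelmap carries the assigned codes
  lm <- as_level_labelmap(s)
  expect_equal(sort(unique(as.vector(lm$values[lm$values > 0]))),
               ph$levels$level_code)
})

test_that("one uncorrected fusion offsets exactly one side by one level", {
  ph <- generate_phantom(phantom_spec(n_vertebrae = 6, first_level = "T7",
                                      seed = 47))
  # fusion of (2,3); every instance except 1 is de-anchored by 10% mixing
  mis <- lapply(2:6, function(i) {
    list(instance = i, level = min(ph$levels$level_code[i] + 1L, 17L),
         fraction = 0.10)
  })
  pred <- corrupt_prediction(ph$instances, ph$levels,
                             corruption_spec(fuse_pairs = list(c(2, 3)),
                                             mislabel = mis, seed = 48))
  ls <- sequential_approach(pred$binary, pred$level,
                            refine_config(split = FALSE))
  expect_equal(nrow(ls$table), 5L)  # merge uncorrected
  m <- match_and_score(ls, ph$instances, ph$levels)
  # above the fusion: correct; below: off by exactly -1
  expect_true(m$label_correct[1])
  expect_equal(m$offset[4:6], rep(-1L, 3))
  expect_true(all(m$offset_attributed[4:6]))
  expect_false(any(m$offset_attributed[1:3]))
})
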