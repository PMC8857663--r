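test_that("dice matches direct voxel counting", {
  a <- array(FALSE, c(10, 10, 10)); a[1:100] <- TRUE
  b <- array(FALSE, c(10, 10, 10)); b[41:120] <- TRUE
  expect_equal(dice(a, b), 120 / 180)  # |a|=100, |b|=80, overlap 60
  expect_equal(dice(a, a), 1.0)
  expect_equal(dice(a, array(FALSE, c(10, 10, 10)) | array(c(rep(FALSE, 900),
                                                             rep(TRUE, 100)),
                                                           c(10, 10, 10))), 0)
  empty <- array(FALSE, c(3, 3, 3))
  expect_equal(dice(empty, empty), 1.0)
  expect_error(dice(a, array(TRUE, c(5, 5, 5))), "misaligned")
})

test_that("hausdorff handles the elementary geometric cases", {
  a <- array(FALSE, c(8, 8, 8)); a[2, 2, 2] <- TRUE
  b <- array(FALSE, c(8, 8, 8)); b[2, 2, 5] <- TRUE
  expect_equal(hausdorff(a, b), 3.0)
  expect_equal(hausdorff(a, a), 0.0)

  # cube vs the same cube shifted 2 voxels at unit spacing
  c1 <- array(FALSE, c(10, 10, 10)); c1[3:5, 3:5, 3:5] <- TRUE
  c2 <- array(FALSE, c(10, 10, 10)); c2[3:5, 3:5, 5:7] <- TRUE
  expect_equal(hausdorff(c1, c2), 2.0)
  # symmetry
  expect_equal(hausdorff(c2, c1), hausdorff(c1, c2))
  # spacing scales distances
  expect_equal(hausdorff(a, b, spacing = c(1, 1, 2)), 6.0)
  expect_error(hausdorff(a, array(FALSE, c(8, 8, 8))), "empty")
})

test_that("dice and hausdorff agree with brute-force oracles", {
  for (seed in 1:10) {
    d <- c(sample(6:15, 1), sample(6:15, 1), sample(6:15, 1))
    a <- random_mask(d, 0.3, seed = 200 + seed)
    b <- random_mask(d, 0.3, seed = 300 + seed)
    expect_identical(dice(a, b), brute_dice(a, b))
    expect_equal(hausdorff(a, b), brute_hausdorff(a, b), tolerance = 1e-9)
    sp <- c(0.7, 1.1, 1.6)
    expect_equal(hausdorff(a, b, sp), brute_hausdorff(a, b, sp),
                 tolerance = 1e-9)
  }
})

test_that("perfect predictions score perfectly; unmatched vertebrae are flagged", {
  ph <- generate_phantom(phantom_spec(n_vertebrae = 5, seed = 51))
  pred <- corrupt_prediction(ph$instances, ph$levels, corruption_spec(seed = 52))
  ls <- sequential_approach(pred$binary, pred$level)
  m <- match_and_score(ls, ph$instances, ph$levels)
  expect_equal(nrow(m), 5L)
  expect_true(all(m$label_correct))
  expect_equal(m$dsc, rep(1, 5))
  expect_equal(m$hd_mm, rep(0, 5))

  # erase one gt vertebra from the prediction: DSC 0, HD missing
  arr <- pred$binary$values
  arr[ph$instances$values == 3L] <- 0L
  lvl <- pred$level$values
  lvl[ph$instances$values == 3L] <- 0L
  ls2 <- sequential_approach(
    labelmap3d(arr, spacing = pred$binary$spacing, semantics = "binary"),
    labelmap3d(lvl, spacing = pred$level$spacing, semantics = "level")
  )
  m2 <- match_and_score(ls2, ph$instances, ph$levels)
  row3 <- m2[m2$gt_instance_id == 3L, ]
  expect_equal(row3$dsc, 0)
  expect_true(row3$hd_missing)
  expect_true(is.na(row3$hd_mm))
})

test_that("labeling accuracy reports counts with a Wilson interval", {
  m <- tibble::tibble(label_correct = c(rep(TRUE, 9), FALSE))
  acc <- labeling_accuracy(m)
  expect_equal(acc$accuracy, 0.9)
  expect_equal(acc$n, 10L)
  expect_true(acc$ci_low < 0.9 && acc$ci_high > 0.9)

  none <- tibble::tibble(label_correct = rep(FALSE, 5))
  acc0 <- labeling_accuracy(none)
  expect_equal(acc0$accuracy, 0)
  expect_equal(acc0$ci_low, 0)
  expect_gt(acc0$ci_high, 0)
  expect_error(labeling_accuracy(m[0, ]), "Empty")
})

test_that("paired signed-rank test matches exact enumeration and is symmetric", {
  a <- rep(1, 6)
  b <- 2:7
  res <- compare_paired(a, b, zero_policy = "wilcoxon")
  # all six differences negative: V = 0; exact two-sided p from the 2^6 null
  expect_equal(res$statistic, 0)
  v_null <- vapply(0:63, function(bits) {
    sum(which(bitwAnd(bits, 2^(0:5)) > 0))
  }, numeric(1))
  p_exact <- 2 * mean(v_null <= 0)
  expect_equal(res$p_value, p_exact)
  # swapping the samples leaves the p-value unchanged
  expect_equal(compare_paired(b, a, zero_policy = "wilcoxon")$p_value,
               res$p_value)

  # identical samples: flagged p = 1 path
  same <- compare_paired(a, a)
  expect_true(same$all_zero)
  expect_equal(same$p_value, 1)

  # Pratt reduces to the classical test when no zeros/ties are present
  set.seed(9)
  x <- stats::rnorm(30)
  y <- x + stats::rnorm(30, 0.3)
  pr <- compare_paired(x, y, zero_policy = "pratt")
  wt <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = FALSE)
  expect_equal(pr$statistic, unname(wt$statistic))
  expect_equal(pr$p_value, wt$p.value, tolerance = 1e-10)
  expect_error(compare_paired(1:3, 1:4), "equal length")
})
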