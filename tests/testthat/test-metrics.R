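test_that("confusion counts follow the set-operation definitions", {
  gt <- matrix(FALSE, 10, 10); gt[2:5, 1:10] <- TRUE # 40 px block
  expect_equal(unclass(confusion_counts(gt, gt)),
               list(tp = 40L, fp = 0L, fn = 0L))
  s <- matrix(FALSE, 10, 10); s[7:9, 7:8] <- TRUE # 6 px, disjoint
  gt2 <- matrix(FALSE, 10, 10); gt2[1:2, 1:5] <- TRUE # 10 px
  expect_equal(unclass(confusion_counts(gt2, s)),
               list(tp = 0L, fp = 6L, fn = 10L))
  # 2x2 block vs the same block shifted one column
  gt3 <- matrix(FALSE, 5, 5); gt3[2:3, 2:3] <- TRUE
  s3 <- matrix(FALSE, 5, 5); s3[2:3, 3:4] <- TRUE
  cc <- confusion_counts(gt3, s3)
  expect_equal(unclass(cc), list(tp = 2L, fp = 2L, fn = 2L))
  expect_equal(iou(cc), 1 / 3)
  expect_equal(dice(cc), 0.5)
  expect_error(confusion_counts(gt3, matrix(FALSE, 4, 5)), "shapes")
})

test_that("IoU and Dice endpoints and the both-empty convention", {
  perfect <- confusion_counts(matrix(TRUE, 5, 8), matrix(TRUE, 5, 8))
  expect_equal(iou(perfect), 1)
  expect_equal(dice(perfect), 1)
  none <- structure(list(tp = 0L, fp = 6L, fn = 10L), class = "metric_counts")
  expect_equal(iou(none), 0)
  empty <- confusion_counts(matrix(FALSE, 4, 4), matrix(FALSE, 4, 4))
  expect_equal(as.numeric(iou(empty)), 1)
  expect_true(attr(iou(empty), "degenerate"))
  expect_true(metric_report(matrix(FALSE, 4, 4),
                            matrix(FALSE, 4, 4))$degenerate)
})

test_that("implementation matches a brute-force loop on random masks", {
  set.seed(10)
  for (i in 1:100) {
    gt <- matrix(runif(32 * 32) > runif(1, 0.5, 0.95), 32, 32)
    s <- matrix(runif(32 * 32) > runif(1, 0.5, 0.95), 32, 32)
    cc <- confusion_counts(gt, s)
    bf <- brute_confusion(gt, s)
    expect_identical(cc$tp, bf$tp)
    expect_identical(cc$fp, bf$fp)
    expect_identical(cc$fn, bf$fn)
    # invariants: tp+fn = |gt|, tp+fp = |s|; Dice/IoU relation and bounds
    expect_equal(cc$tp + cc$fn, sum(gt))
    expect_equal(cc$tp + cc$fp, sum(s))
    i1 <- as.numeric(iou(cc)); d1 <- as.numeric(dice(cc))
    expect_equal(d1, 2 * i1 / (1 + i1))
    expect_true(d1 >= i1 && i1 >= 0 && d1 <= 1)
    # Dice is symmetric in swapping fp and fn
    swapped <- structure(list(tp = cc$tp, fp = cc$fn, fn = cc$fp),
                         class = "metric_counts")
    expect_equal(dice(swapped), d1)
  }
})

test_that("mask-set evaluation averages per-image metrics unweighted", {
  gt <- list(matrix(c(TRUE, rep(FALSE, 8)), 3, 3),
             matrix(c(TRUE, TRUE, rep(FALSE, 7)), 3, 3))
  expect_equal(evaluate_masks(gt, gt)$mean_iou, 1)
  expect_equal(evaluate_masks(gt, gt)$mean_dice, 1)
  allbg <- lapply(gt, function(m) m & FALSE)
  expect_equal(evaluate_masks(allbg, gt)$mean_iou, 0)
  # means are the plain average of per-image scores
  p1 <- matrix(FALSE, 2, 5); p1[1, 1] <- TRUE
  g1 <- matrix(FALSE, 2, 5); g1[1, 1:5] <- TRUE   # iou 0.2
  p2 <- matrix(FALSE, 2, 5); p2[1, 1:4] <- TRUE
  g2 <- matrix(FALSE, 2, 5); g2[1, 1:5] <- TRUE   # iou 0.8
  res <- evaluate_masks(list(p1, p2), list(g1, g2))
  expect_equal(res$per_image$iou, c(0.2, 0.8))
  expect_equal(res$mean_iou, 0.5)
  expect_error(evaluate_masks(list(p1), list(g1, g2)), "ground-truth")
})
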