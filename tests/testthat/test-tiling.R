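test_that("grid for the reference device resolution matches the stride rule", {
  plan <- compute_grid(c(2056L, 2124L), tiling_config(576L, 0.30))
  expect_equal(sort(unique(plan$origins$row)), c(0L, 403L, 806L, 1209L, 1480L))
  expect_equal(sort(unique(plan$origins$col)), c(0L, 403L, 806L, 1209L, 1548L))
  expect_equal(nrow(plan$origins), 25L)
})

test_that("window equal to image gives a single origin", {
  plan <- compute_grid(c(576L, 576L), tiling_config(576L, 0.30))
  expect_equal(nrow(plan$origins), 1L)
  expect_equal(unlist(plan$origins[1, ]), c(row = 0L, col = 0L))
})

test_that("edge-anchored origin is added when the stride overshoots", {
  plan <- compute_grid(c(576L, 700L), tiling_config(576L, 0.30))
  expect_equal(sort(unique(plan$origins$col)), c(0L, 124L))
  expect_equal(unique(plan$origins$row), 0L)
  expect_equal(nrow(plan$origins), 2L)
})

test_that("plans cover every pixel for a sweep of sizes and overlaps", {
  set.seed(1)
  for (i in 1:12) {
    w <- sample(8:32, 1)
    h <- w + sample(0:40, 1)
    ww <- w + sample(0:40, 1)
    ov <- runif(1, 0, 0.9)
    cfg <- tiling_config(w, ov)
    plan <- compute_grid(c(h, ww), cfg)
    cover <- matrix(0L, h, ww)
    for (k in seq_len(nrow(plan$origins))) {
      r <- plan$origins$row[k]; cc <- plan$origins$col[k]
      cover[r + seq_len(w), cc + seq_len(w)] <-
        cover[r + seq_len(w), cc + seq_len(w)] + 1L
    }
    expect_true(all(cover >= 1L))
    expect_false(any(duplicated(plan$origins)))
  }
})

test_that("raising overlap never decreases origins per axis", {
  n_rows <- sapply(seq(0, 0.9, by = 0.1), function(ov) {
    length(unique(compute_grid(c(300L, 300L),
                               tiling_config(64L, ov))$origins$row))
  })
  expect_true(all(diff(n_rows) >= 0))
})

test_that("images smaller than the window are rejected with advice", {
  expect_error(compute_grid(c(100L, 700L), tiling_config(576L)),
               "pad the image|smaller window")
})

test_that("all-black patches are discarded, others kept", {
  cfg <- tiling_config(16L, 0.25)
  img <- array(0, c(32L, 48L, 3L))
  plan <- compute_grid(dim(img)[1:2], cfg)
  rois <- extract_rois(img, plan, cfg)
  expect_length(rois, 0L)
  expect_equal(attr(rois, "n_discarded"), nrow(plan$origins))
  # one bright pixel at (1, 1): exactly the windows containing it are kept
  img[1, 1, 1] <- 1
  rois <- extract_rois(img, plan, cfg)
  contains_origin <- plan$origins$row == 0L & plan$origins$col == 0L
  expect_length(rois, sum(contains_origin))
  expect_equal(nrow(attr(rois, "manifest")), nrow(plan$origins))
  # strict rule: an 8-bit value of 1 is not black at black_tol = 0
  img2 <- array(0, c(16L, 16L, 3L))
  img2[8, 8, 2] <- 1 / 255
  plan2 <- compute_grid(c(16L, 16L), tiling_config(16L))
  expect_length(extract_rois(img2, plan2, tiling_config(16L)), 1L)
  expect_length(extract_rois(img2, plan2, tiling_config(16L, black_tol = 1L)),
                0L)
})

test_that("accumulation adds probabilities and counts on the window", {
  cv <- probability_canvas(c(8L, 8L))
  cv <- accumulate_patch(cv, c(0L, 0L), matrix(0.7, 4, 4))
  expect_equal(cv$prob_sum[1:4, 1:4], matrix(0.7, 4, 4))
  expect_equal(cv$count[1:4, 1:4], matrix(1L, 4, 4))
  expect_true(all(cv$count[5:8, ] == 0L))
  cv <- accumulate_patch(cv, c(0L, 0L), matrix(0.2, 4, 4))
  expect_equal(cv$prob_sum[1, 1], 0.9)
  expect_equal(cv$count[1, 1], 2L)
  expect_error(accumulate_patch(cv, c(6L, 6L), matrix(0.5, 4, 4)),
               "does not fit")
  expect_error(accumulate_patch(cv, c(0L, 0L), matrix(1.5, 4, 4)),
               "\\[0, 1\\]")
})

test_that("accumulation is order-invariant and finalize averages", {
  set.seed(2)
  cfg <- tiling_config(8L, 0.4)
  plan <- compute_grid(c(20L, 20L), cfg)
  patches <- lapply(seq_len(nrow(plan$origins)),
                    function(i) matrix(runif(64), 8, 8))
  run <- function(ord) {
    cv <- probability_canvas(c(20L, 20L))
    for (i in ord)
      cv <- accumulate_patch(cv, unlist(plan$origins[i, ]), patches[[i]])
    cv
  }
  a <- run(seq_len(nrow(plan$origins)))
  b <- run(sample(nrow(plan$origins)))
  expect_identical(a$count, b$count)
  expect_equal(a$prob_sum, b$prob_sum, tolerance = 1e-12)
  expect_equal(finalize_map(a), a$prob_sum / a$count)
})

test_that("patches cut from a probability map reconstruct it exactly", {
  set.seed(3)
  P <- matrix(runif(30 * 26), 30, 26)
  cfg <- tiling_config(10L, 0.3)
  plan <- compute_grid(dim(P), cfg)
  cv <- probability_canvas(dim(P))
  for (i in seq_len(nrow(plan$origins))) {
    r <- plan$origins$row[i]; cc <- plan$origins$col[i]
    cv <- accumulate_patch(cv, c(r, cc), P[r + 1:10, cc + 1:10])
  }
  expect_equal(finalize_map(cv), P, tolerance = 1e-12)
})

test_that("finalize refuses uncovered pixels and names one", {
  cv <- probability_canvas(c(6L, 6L))
  cv <- accumulate_patch(cv, c(0L, 0L), matrix(0.5, 4, 4))
  expect_error(finalize_map(cv), "uncovered")
})

test_that("threshold is strictly greater-than", {
  m <- matrix(c(0, 0.5, 0.51, 1), 2, 2)
  out <- threshold_map(m, 0.5)
  expect_identical(out, matrix(c(FALSE, FALSE, TRUE, TRUE), 2, 2))
  expect_false(any(threshold_map(matrix(0, 3, 3))))
  expect_error(threshold_map(m, 1.2), "tau")
})
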