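tiny_members <- function(seed = 1L) {
  list(
    unet = build_unet(model_config("unet", input_size = 32L, base_width = 4L,
                                   depth = 2L, bottleneck_width = 16L,
                                   seed = seed)),
    resnet34_unet = build_resnet34_unet(
      model_config("resnet34_unet", input_size = 32L, base_width = 4L,
                   seed = seed + 1L)),
    unetpp = build_unetpp(model_config("unetpp", input_size = 32L,
                                       base_width = 4L, depth = 2L,
                                       seed = seed + 2L)))
}

test_that("ensemble prediction is the pixelwise mean of the members", {
  set.seed(30)
  ms <- tiny_members()
  ens <- seg_ensemble(ms$unet, ms$resnet34_unet, ms$unetpp)
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  probs <- lapply(ms, predict_patch_batch, x = x)
  got <- predict_patch_batch(ens, x)
  expect_equal(got, (probs[[1]] + probs[[2]] + probs[[3]]) / 3,
               tolerance = 1e-12)
  # mean stays inside the member min-max envelope
  expect_true(all(got >= pmin(probs[[1]], probs[[2]], probs[[3]])))
  expect_true(all(got <= pmax(probs[[1]], probs[[2]], probs[[3]])))
  # single-patch interface agrees
  p1 <- ensemble_predict_patch(ens, x[, , , 1])
  expect_equal(p1, got[, , 1], tolerance = 1e-12)
})

test_that("an ensemble of identical members equals the member", {
  m <- tiny_unet(seed = 5L)
  # membership is validated by architecture, so wrap the same weights
  ms <- tiny_members(seed = 7L)
  ens <- seg_ensemble(m, ms$resnet34_unet, ms$unetpp)
  ens$members <- list(unet = m, resnet34_unet = m, unetpp = m)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
  expect_equal(predict_patch_batch(ens, x), predict_patch_batch(m, x),
               tolerance = 1e-12)
})

test_that("member architecture slots are validated", {
  ms <- tiny_members()
  expect_error(seg_ensemble(ms$resnet34_unet, ms$unet, ms$unetpp),
               "built as")
  expect_error(seg_ensemble(ms$unet, ms$resnet34_unet, list()),
               "not a seg_model")
})

test_that("whole-image prediction with stub predictors", {
  img <- generate_sample(synth_config(seed = 9L, image_size = c(150L, 170L),
                                      n_mas = 3L,
                                      ma_diameter_range = c(5, 20)))
  cfg <- tiling_config(64L, 0.30)
  # constant 0.7: uniform map, everything segmented (0.7 > 0.5)
  const <- function(x) array(0.7, dim(x)[c(1, 2, 4)])
  res <- predict_image(img$image, const, cfg)
  expect_equal(res$prob_map, matrix(0.7, 150, 170), tolerance = 1e-12)
  expect_true(all(res$mask))
  # constant 0.5 is NOT above the strict threshold: all background
  res5 <- predict_image(img$image, function(x) array(0.5, dim(x)[c(1, 2, 4)]),
                        cfg)
  expect_false(any(res5$mask))
  # a stub that returns the ground truth as {0,1} probabilities, served in
  # plan order, reconstructs the ground-truth mask exactly
  plan <- compute_grid(dim(img$image)[1:2], cfg)
  k <- 0L
  oracle <- function(x) {
    n <- dim(x)[4]
    out <- array(0, dim(x)[c(1, 2, 4)])
    for (i in seq_len(n)) {
      k <<- k + 1L
      r <- plan$origins$row[k]; cc <- plan$origins$col[k]
      out[, , i] <- img$mask[r + 1:64, cc + 1:64]
    }
    out
  }
  res_gt <- predict_image(img$image, oracle, cfg)
  expect_identical(res_gt$mask, img$mask)
})

test_that("trained-model whole-image prediction returns valid outputs", {
  set.seed(31)
  m <- tiny_unet(seed = 6L)
  s <- generate_sample(synth_config(seed = 12L, image_size = c(96L, 96L),
                                    n_mas = 2L, ma_diameter_range = c(5, 12)))
  res <- predict_image(s$image, m, tiling_config(32L, 0.30))
  expect_equal(dim(res$prob_map), c(96L, 96L))
  expect_true(all(res$prob_map >= 0 & res$prob_map <= 1))
  expect_identical(res$mask, res$prob_map > 0.5)
})

test_that("majority voting combiner is available and binary", {
  ms <- tiny_members(seed = 9L)
  ens <- seg_ensemble(ms$unet, ms$resnet34_unet, ms$unetpp, combine = "vote")
  x <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
  p <- predict_patch_batch(ens, x)
  expect_true(all(p %in% c(0, 1)))
})
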