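test_that("split sizes follow the 70/10/20 protocol", {
  sp <- split_patches(as.list(1:1000), split_spec(seed = 3L))
  expect_equal(vapply(sp, length, integer(1)),
               c(train = 700L, val = 100L, test = 200L))
  sp10 <- split_patches(as.list(1:10), split_spec(seed = 3L))
  expect_equal(vapply(sp10, length, integer(1)),
               c(train = 7L, val = 1L, test = 2L))
})

test_that("splits are deterministic, disjoint and exhaustive", {
  items <- as.list(1:137)
  a <- split_patches(items, split_spec(seed = 11L))
  b <- split_patches(items, split_spec(seed = 11L))
  expect_identical(a, b)
  all_items <- c(unlist(a$train), unlist(a$val), unlist(a$test))
  expect_setequal(all_items, 1:137)
  expect_equal(length(all_items), 137L)
  d <- split_patches(items, split_spec(seed = 12L))
  expect_false(identical(unlist(a$train), unlist(d$train)))
})

test_that("invalid split fractions are rejected", {
  expect_error(split_spec(0.7, 0.2, 0.2), "sum to 1")
  expect_error(split_patches(as.list(1:5), split_spec()), "at least 10")
})

test_that("patch dataset aligns image and mask crops", {
  s <- generate_sample(synth_config(seed = 5L, image_size = c(96L, 96L),
                                    n_mas = 3L, ma_diameter_range = c(5, 15)))
  ds <- make_patch_dataset(list(s), tiling_config(32L, 0.25))
  expect_true(length(ds) > 0)
  for (p in ds[1:3]) {
    expect_equal(dim(p$x), c(32L, 32L, 3L))
    expect_equal(dim(p$y), c(32L, 32L))
    expect_identical(p$y, s$mask[p$row + 1:32, p$col + 1:32])
  }
  # total foreground in patches covers every masked pixel at least once
  got <- matrix(FALSE, 96, 96)
  for (p in ds) got[p$row + 1:32, p$col + 1:32] <- got[p$row + 1:32,
                                                       p$col + 1:32] | p$y
  expect_identical(got, s$mask)
})

test_that("a short training run completes with finite loss, deterministically", {
  set.seed(20)
  train <- replicate(8, random_patch_pair(16L, fg = TRUE), simplify = FALSE)
  run <- function() {
    m <- build_unet(model_config("unet", input_size = 16L, base_width = 4L,
                                 depth = 2L, bottleneck_width = 16L,
                                 seed = 2L))
    train_model(m, train, list(), train_config(epochs = 1L, seed = 9L))
  }
  m1 <- run(); m2 <- run()
  expect_true(is.finite(m1$history$loss))
  expect_identical(m1$history$loss, m2$history$loss)
  expect_identical(m1$params, m2$params)
  expect_error(train_model(m1, list(), list(), train_config()), "empty")
})

test_that("training on all-background masks drives foreground mass down", {
  set.seed(21)
  train <- replicate(10, random_patch_pair(16L, fg = FALSE), simplify = FALSE)
  m <- build_unet(model_config("unet", input_size = 16L, base_width = 4L,
                               depth = 2L, bottleneck_width = 16L, seed = 3L))
  m <- train_model(m, train, list(), train_config(epochs = 4L, seed = 10L))
  fg <- m$history$mean_fg_prob
  expect_lt(fg[length(fg)], fg[1])
})

test_that("best-validation-Dice weights are the ones returned", {
  set.seed(22)
  train <- replicate(10, random_patch_pair(16L, fg = TRUE), simplify = FALSE)
  val <- replicate(4, random_patch_pair(16L, fg = TRUE), simplify = FALSE)
  m <- build_unet(model_config("unet", input_size = 16L, base_width = 4L,
                               depth = 2L, bottleneck_width = 16L, seed = 4L))
  m <- train_model(m, train, val, train_config(epochs = 3L, seed = 11L))
  best_epoch_dice <- max(m$history$val_dice)
  got <- maseg:::.pooled_dice(m, val)
  expect_equal(got, best_epoch_dice)
})
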