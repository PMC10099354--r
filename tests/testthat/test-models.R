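test_that("reference parameter counts meet the architecture floors", {
  unet <- build_unet(init = FALSE)
  expect_gte(count_parameters(unet), 7.7e6)
  res <- build_resnet34_unet(init = FALSE)
  expect_gte(count_parameters(res), 21.6e6)
  # counts derive from configuration alone, never from weights
  expect_identical(count_parameters(build_unet(init = TRUE)),
                   count_parameters(unet))
})

test_that("layer-level parameter counting is exact", {
  ns <- asNamespace("maseg")
  g <- ns$new_graph()
  i <- ns$g_input(g, 3L)
  ns$g_conv(g, i, 3L, 8L) # single 3x3 convolution, 3 -> 8, with bias
  expect_equal(ns$net_param_count(list(ops = g$ops)), (3 * 3 * 3 + 1) * 8)
  g2 <- ns$new_graph()
  i2 <- ns$g_input(g2, 32L)
  ns$g_conv(g2, i2, 32L, 2L, k = 1L, pad = 0L) # 1x1, 32 -> 2
  expect_equal(ns$net_param_count(list(ops = g2$ops)), (32 + 1) * 2)
})

test_that("freezing the ResNet34 encoder removes at least half the count", {
  full <- count_parameters(build_resnet34_unet(init = FALSE))
  frozen <- count_parameters(build_resnet34_unet(init = FALSE,
                                                 freeze_encoder = TRUE))
  expect_lte(frozen, full / 2)
})

test_that("U-Net++ deep supervision only adds the extra 1x1 heads", {
  base <- model_config("unetpp", input_size = 32L, base_width = 4L, depth = 3L)
  ds <- model_config("unetpp", input_size = 32L, base_width = 4L, depth = 3L,
                     deep_supervision = TRUE)
  n0 <- count_parameters(build_unetpp(base, init = FALSE))
  n1 <- count_parameters(build_unetpp(ds, init = FALSE))
  # heads: one (w0+1)*2 1x1 conv per top-level node; plain config has 1 of 3
  extra_heads <- (3 - 1) * (4 + 1) * 2
  expect_equal(n1 - n0, extra_heads)
})

test_that("all three scaled-down models honor the prediction contract", {
  set.seed(4)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  models <- list(
    build_unet(model_config("unet", input_size = 32L, base_width = 4L,
                            depth = 2L, bottleneck_width = 16L)),
    build_resnet34_unet(model_config("resnet34_unet", input_size = 32L,
                                     base_width = 4L)),
    build_unetpp(model_config("unetpp", input_size = 32L, base_width = 4L,
                              depth = 2L)))
  for (m in models) {
    p <- predict_patch(m, x)
    expect_equal(dim(p), c(32L, 32L))
    expect_true(all(p >= 0 & p <= 1))
    # deterministic for fixed weights and input
    expect_identical(p, predict_patch(m, x))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(model_config("unet", input_size = 100L, depth = 5L),
               "divisible")
  expect_error(model_config("resnet34_unet", pretrained_encoder = TRUE),
               "pretrained")
  expect_error(build_resnet34_unet(model_config("resnet34_unet",
                                                input_size = 576L)),
               NA)
})

test_that("a residual block with zeroed convolutions is ReLU(identity)", {
  ns <- asNamespace("maseg")
  g <- ns$new_graph()
  i <- ns$g_input(g, 3L)
  ns$.res_block(g, i, 3L, 3L, 1L)
  net <- list(ops = g$ops)
  params <- ns$net_init_params(net, seed = 1)
  for (nm in names(params)) {
    if (grepl("\\.(W|b|beta)$", nm)) params[[nm]] <- params[[nm]] * 0
  }
  x <- array(rnorm(6 * 6 * 3 * 2), c(6, 6, 3, 2))
  out <- ns$net_forward(net, params, x, training = FALSE)$out
  expect_equal(out, x * (x > 0), tolerance = 1e-12)
})

test_that("convolution kernels match a direct-convolution oracle", {
  set.seed(5)
  ns <- asNamespace("maseg")
  cases <- list(list(k = 3L, stride = 1L, pad = 1L),   # fast tap-GEMM path
                list(k = 1L, stride = 1L, pad = 0L),   # fast 1x1 path
                list(k = 7L, stride = 2L, pad = 3L),   # generic stem path
                list(k = 3L, stride = 2L, pad = 1L))   # generic strided path
  for (cs in cases) {
    x <- array(rnorm(12 * 10 * 3 * 2), c(12, 10, 3, 2))
    Wm <- matrix(rnorm(cs$k^2 * 3 * 4), cs$k^2 * 3, 4)
    b <- rnorm(4)
    got <- ns$.conv_fwd(x, Wm, b, cs$k, cs$stride, cs$pad)
    want <- conv_oracle(x, Wm, b, cs$k, cs$stride, cs$pad)
    expect_equal(array(got, dim(got)), want, tolerance = 1e-12)
  }
})

test_that("analytic gradients agree with finite differences", {
  set.seed(6)
  ns <- asNamespace("maseg")
  m <- tiny_unet(seed = 8L, input = 16L)
  x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  y <- array(runif(16 * 16 * 2) > 0.8, c(16, 16, 2))
  params <- m$params
  fwd <- ns$net_forward(m$net, params, x, training = TRUE)
  l <- ns$softmax_ce(fwd$out, y)
  grads <- ns$net_backward(m$net, params, fwd, l$dlogits)
  loss_at <- function(p) {
    f <- ns$net_forward(m$net, p, x, training = TRUE)
    ns$softmax_ce(f$out, y)$loss
  }
  eps <- 1e-6
  nms <- sample(ns$net_trainable_names(m$net), 6)
  for (nm in nms) {
    i <- sample(length(params[[nm]]), 1)
    pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
    pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
    gnum <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
    expect_equal(grads[[nm]][i], gnum, tolerance = 1e-4)
  }
})

test_that("checkpoints round-trip with an auditable sidecar", {
  m <- tiny_unet()
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_identical(predict_patch(m, x), predict_patch(m2, x))
  sidecar <- readLines(paste0(path, ".config.txt"))
  expect_true(any(grepl("arch: unet", sidecar)))
  expect_true(any(grepl(sprintf("trainable_parameters: %d",
                                count_parameters(m)), sidecar)))
})
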