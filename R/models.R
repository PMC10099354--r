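#' Segmentation model configuration
#'
#' Describes one of the three encoder-decoder architectures used by the
#' ensemble: a classic U-Net, a ResNet34-encoder U-Net with additive
#' attention gates on the skip connections, and a U-Net++ with nested dense
#' skip connections. The reference configurations operate on 576 x 576 RGB
#' patches and reach an 18 x 18 x 512 bottleneck after five down-sampling
#' stages.
#'
#' @param arch One of `"unet"`, `"resnet34_unet"`, `"unetpp"`.
#' @param input_size Patch side length in pixels. Must be divisible by
#'   `2^depth` (`32` for the ResNet34 encoder).
#' @param in_channels Number of input channels (3 for RGB fundus patches).
#' @param base_width Channels at the first encoder stage. Defaults: 16
#'   (unet), 64 (resnet34_unet), 32 (unetpp).
#' @param depth Number of down-sampling stages. Defaults: 5 (unet),
#'   4 (unetpp); fixed at 5 for the ResNet34 encoder.
#' @param bottleneck_width Channels at the deepest stage (unet only,
#'   default 512).
#' @param deep_supervision U-Net++ only: attach auxiliary 1x1 heads to the
#'   intermediate top-level nodes and average their outputs.
#' @param attention_gates ResNet34-UNet only: additive attention gate on
#'   each skip connection (default `TRUE`).
#' @param pretrained_encoder ResNet34-UNet only. No encoder weights are
#'   bundled, so this must remain `FALSE`; requesting it raises an error
#'   explaining how to train offline instead.
#' @param seed Seed used for weight initialization.
#' @return A `model_config` object (a list).
#' @export
model_config <- function(arch = c("unet", "resnet34_unet", "unetpp"),
                         input_size = 576L, in_channels = 3L,
                         base_width = NULL, depth = NULL,
                         bottleneck_width = NULL,
                         deep_supervision = FALSE,
                         attention_gates = TRUE,
                         pretrained_encoder = FALSE,
                         seed = 42L) {
  arch <- match.arg(arch)
  if (is.null(base_width))
    base_width <- switch(arch, unet = 16L, resnet34_unet = 64L, unetpp = 32L)
  if (is.null(depth))
    depth <- switch(arch, unet = 5L, resnet34_unet = 5L, unetpp = 4L)
  if (is.null(bottleneck_width))
    bottleneck_width <- if (arch == "unet") 512L else NA_integer_
  if (arch == "resnet34_unet") depth <- 5L
  stopifnot(base_width >= 1, depth >= 1, input_size >= 2^depth)
  if (input_size %% 2^depth != 0)
    stop("input_size ", input_size, " is not divisible by 2^depth = ",
         2^depth)
  if (pretrained_encoder)
    stop("no pretrained encoder weights are bundled; train from the ",
         "seeded random initialization instead (pretrained_encoder = FALSE)")
  structure(list(arch = arch, input_size = as.integer(input_size),
                 in_channels = as.integer(in_channels),
                 base_width = as.integer(base_width),
                 depth = as.integer(depth),
                 bottleneck_width = as.integer(bottleneck_width),
                 deep_supervision = isTRUE(deep_supervision),
                 attention_gates = isTRUE(attention_gates),
                 pretrained_encoder = FALSE,
                 seed = as.integer(seed)),
            class = "model_config")
}

# two 3x3 convolutions, each followed by batch norm and ReLU
.conv_block <- function(g, x, cin, cout) {
  c1 <- g_conv(g, x, cin, cout)
  r1 <- g_relu(g, g_bn(g, c1, cout), cout)
  c2 <- g_conv(g, r1, cout, cout)
  g_relu(g, g_bn(g, c2, cout), cout)
}

.finish_model <- function(g, config, encoder_par_names = character(),
                          init = TRUE) {
  net <- list(ops = g$ops)
  model <- structure(
    list(config = config, net = net,
         parameter_count = net_param_count(net),
         encoder_par_names = encoder_par_names,
         params = NULL),
    class = "seg_model")
  if (init) model$params <- net_init_params(net, seed = config$seed)
  model
}

#' Build the U-Net segmentation model
#'
#' Encoder of `depth` stages (two 3x3 convolutions + batch norm + ReLU,
#' then 2x2 max pooling, widths doubling from `base_width`), a bottleneck
#' block of `bottleneck_width` channels, and a mirrored decoder with 2x2
#' transposed-convolution up-sampling and skip concatenations. The head is
#' a 1x1 convolution with a two-channel softmax; the foreground channel is
#' the microaneurysm probability. The reference configuration (input 576,
#' depth 5, widths 16..256, bottleneck 512) has about 7.78 million
#' trainable parameters and an 18 x 18 x 512 bottleneck.
#'
#' @param config A [model_config()] with `arch = "unet"`.
#' @param init Initialize weights (He-normal, seeded)? Parameter counting
#'   does not require weights.
#' @return A `seg_model`.
#' @export
build_unet <- function(config = model_config("unet"), init = TRUE) {
  stopifnot(inherits(config, "model_config"), config$arch == "unet")
  g <- new_graph()
  inp <- g_input(g, config$in_channels)
  widths <- config$base_width * 2^(seq_len(config$depth) - 1L)
  skips <- integer(config$depth)
  cur <- inp
  cin <- config$in_channels
  for (i in seq_len(config$depth)) {
    skips[i] <- .conv_block(g, cur, cin, widths[i])
    cur <- g_pool(g, skips[i], widths[i])
    cin <- widths[i]
  }
  bw <- config$bottleneck_width
  cur <- .conv_block(g, cur, cin, bw)
  cw <- bw
  for (i in rev(seq_len(config$depth))) {
    up <- g_upconv2(g, cur, cw, widths[i])
    cat <- g_concat(g, c(up, skips[i]), c(widths[i], widths[i]))
    cur <- .conv_block(g, cat, 2L * widths[i], widths[i])
    cw <- widths[i]
  }
  g_conv(g, cur, cw, 2L, k = 1L, pad = 0L)
  .finish_model(g, config, init = init)
}

# one residual unit: conv3-BN-ReLU-conv3-BN, shortcut added before final
# ReLU. The second BN's gamma starts at zero so each block begins as the
# identity map, which keeps the 16-block encoder trainable from random
# initialization regardless of seed.
.res_block <- function(g, x, cin, cout, stride = 1L) {
  c1 <- g_conv(g, x, cin, cout, k = 3L, stride = stride)
  r1 <- g_relu(g, g_bn(g, c1, cout), cout)
  c2 <- g_conv(g, r1, cout, cout)
  b2 <- g_bn(g, c2, cout, gamma_init = 0)
  sc <- if (stride != 1L || cin != cout) {
    g_bn(g, g_conv(g, x, cin, cout, k = 1L, stride = stride, pad = 0L), cout)
  } else {
    x
  }
  g_relu(g, g_addop(g, b2, sc, cout), cout)
}

# additive attention gate: skip is re-weighted by a sigmoid map computed
# from the skip and the gating (decoder) feature at the same resolution.
# The sigmoid head starts at +3 bias with near-zero weights, so gates open
# uniformly near 1 (pass-through) and learn to suppress; a saturated gate
# at initialization blocks both the skip signal and its gradient.
.attention_gate <- function(g, skip, gate, skip_ch, gate_ch) {
  ci <- max(skip_ch %/% 2L, 1L)
  theta <- g_conv(g, skip, skip_ch, ci, k = 1L, pad = 0L)
  phi   <- g_conv(g, gate, gate_ch, ci, k = 1L, pad = 0L)
  f     <- g_relu(g, g_addop(g, theta, phi, ci), ci)
  att   <- g_sigmoid(g, g_conv(g, f, ci, 1L, k = 1L, pad = 0L,
                               bias_init = 3, w_sd = 0.01), 1L)
  g_scale(g, skip, att, skip_ch)
}

#' Build the ResNet34-UNet segmentation model
#'
#' The encoder is the standard ResNet34 convolutional body (7x7 stride-2
#' stem, 3x3 stride-2 max pool, residual stages of 3/4/6/3 blocks with
#' widths 64/128/256/512 at the reference `base_width = 64`). At input 576
#' the deepest feature is 18 x 18 x 512. The decoder has five
#' transposed-convolution up-sampling blocks (reference widths
#' 256/128/64/32/16) with skip concatenations from the residual stages and
#' the stem; an additive attention gate re-weights each skip when
#' `attention_gates` is on. The input image itself is concatenated before
#' the final block so the head sees original pixel values. The reference
#' configuration has about 24.5 million trainable parameters.
#'
#' @param config A [model_config()] with `arch = "resnet34_unet"`.
#' @param init Initialize weights?
#' @param freeze_encoder Mark encoder parameters non-trainable (they are
#'   then excluded from [count_parameters()] and from optimizer updates).
#' @return A `seg_model`.
#' @export
build_resnet34_unet <- function(config = model_config("resnet34_unet"),
                                init = TRUE, freeze_encoder = FALSE) {
  stopifnot(inherits(config, "model_config"), config$arch == "resnet34_unet")
  if (config$input_size %% 32L != 0)
    stop("input_size must be divisible by 32 for the ResNet34 encoder")
  b <- config$base_width
  g <- new_graph()
  inp <- g_input(g, config$in_channels)
  stem_c <- g_conv(g, inp, config$in_channels, b, k = 7L, stride = 2L, pad = 3L)
  s0 <- g_relu(g, g_bn(g, stem_c, b), b)           # 1/2 resolution
  cur <- g_pool(g, s0, b, k = 3L, stride = 2L, pad = 1L) # 1/4
  blocks <- c(3L, 4L, 6L, 3L)
  widths <- b * c(1L, 2L, 4L, 8L)
  stage_out <- integer(4)
  cin <- b
  for (s in seq_len(4)) {
    for (j in seq_len(blocks[s])) {
      stride <- if (s > 1L && j == 1L) 2L else 1L
      cur <- .res_block(g, cur, cin, widths[s], stride)
      cin <- widths[s]
    }
    stage_out[s] <- cur
  }
  encoder_last_op <- length(g$ops)
  dec_w <- pmax(as.integer(round(b * c(4, 2, 1, 0.5, 0.25))), 8L)
  skip_ids <- c(stage_out[3], stage_out[2], stage_out[1], s0, inp)
  skip_ch  <- c(widths[3], widths[2], widths[1], b, config$in_channels)
  cw <- widths[4]
  for (i in seq_len(5)) {
    up <- g_upconv2(g, cur, cw, dec_w[i])
    skip <- skip_ids[i]
    if (config$attention_gates && skip_ch[i] > 1L)
      skip <- .attention_gate(g, skip, up, skip_ch[i], dec_w[i])
    cat <- g_concat(g, c(up, skip), c(dec_w[i], skip_ch[i]))
    cur <- .conv_block(g, cat, dec_w[i] + skip_ch[i], dec_w[i])
    cw <- dec_w[i]
  }
  g_conv(g, cur, cw, 2L, k = 1L, pad = 0L)
  enc_names <- unlist(lapply(g$ops[seq_len(encoder_last_op)], op_par_names))
  if (freeze_encoder) {
    for (id in seq_len(encoder_last_op)) {
      tr <- g$ops[[id]]$trainable
      if (length(tr))
        g$ops[[id]]$trainable <- stats::setNames(rep(FALSE, length(tr)),
                                                 names(tr))
    }
  }
  .finish_model(g, config, encoder_par_names = enc_names, init = init)
}

#' Build the U-Net++ segmentation model
#'
#' Nested dense-skip topology: node `X(i, j)` receives the up-sampled
#' `X(i+1, j-1)` concatenated with all previous nodes `X(i, 0..j-1)` at the
#' same resolution; every node is two 3x3 convolutions with batch norm and
#' ReLU. With `deep_supervision` on, 1x1 heads are attached to
#' `X(0, 1..depth)` and their logits averaged; otherwise only `X(0, depth)`
#' feeds the head. With the nested nodes removed the connectivity reduces
#' to a plain U-Net.
#'
#' @param config A [model_config()] with `arch = "unetpp"`.
#' @param init Initialize weights?
#' @return A `seg_model`.
#' @export
build_unetpp <- function(config = model_config("unetpp"), init = TRUE) {
  stopifnot(inherits(config, "model_config"), config$arch == "unetpp")
  L <- config$depth
  g <- new_graph()
  inp <- g_input(g, config$in_channels)
  widths <- config$base_width * 2^(0:L)
  X <- matrix(NA_integer_, nrow = L + 1L, ncol = L + 1L) # X[i+1, j+1]
  cin <- config$in_channels
  for (i in 0:L) {
    src <- if (i == 0L) inp else g_pool(g, X[i, 1L], widths[i])
    prev_c <- if (i == 0L) cin else widths[i]
    X[i + 1L, 1L] <- .conv_block(g, src, prev_c, widths[i + 1L])
  }
  for (j in 1:L) {
    for (i in 0:(L - j)) {
      up <- g_upconv2(g, X[i + 2L, j], widths[i + 2L], widths[i + 1L])
      ins <- c(X[i + 1L, 1:j], up)
      chs <- c(rep(widths[i + 1L], j), widths[i + 1L])
      cat <- g_concat(g, ins, chs)
      X[i + 1L, j + 1L] <- .conv_block(g, cat, sum(chs), widths[i + 1L])
    }
  }
  if (config$deep_supervision) {
    heads <- vapply(1:L, function(j)
      g_conv(g, X[1L, j + 1L], widths[1L], 2L, k = 1L, pad = 0L), integer(1))
    g_mean(g, heads, 2L)
  } else {
    g_conv(g, X[1L, L + 1L], widths[1L], 2L, k = 1L, pad = 0L)
  }
  .finish_model(g, config, init = init)
}

#' Count trainable parameters
#'
#' Sums all trainable weights and biases (batch-norm running statistics are
#' buffers, not parameters, and are excluded). The count is a function of
#' the configuration alone and never depends on weight values or inputs.
#'
#' @param model A `seg_model`.
#' @return Integer-valued count of trainable parameters.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "seg_model"))
  net_param_count(model$net)
}

#' Predict a probability map for one patch
#'
#' Runs the network in inference mode on a single `window x window x 3`
#' patch with values in \[0, 1\] and returns the per-pixel microaneurysm
#' probability (foreground channel of the softmax head).
#'
#' @param model A `seg_model` with initialized weights, or a `seg_ensemble`.
#' @param patch Numeric array `H x W x 3` in \[0, 1\].
#' @return Numeric `H x W` matrix of probabilities in \[0, 1\].
#' @export
predict_patch <- function(model, patch) {
  p <- predict_patch_batch(model, array(patch, c(dim(patch)[1:2],
                                                 dim(patch)[3], 1L)))
  p[, , 1L]
}

#' Predict probability maps for a batch of patches
#'
#' @param model A `seg_model` or `seg_ensemble`.
#' @param x Numeric array `H x W x C x N` in \[0, 1\].
#' @return Numeric array `H x W x N` of probabilities.
#' @export
predict_patch_batch <- function(model, x) {
  UseMethod("predict_patch_batch")
}

#' @export
predict_patch_batch.seg_model <- function(model, x) {
  if (is.null(model$params))
    stop("model has no weights; build with init = TRUE or train it first")
  fwd <- net_forward(model$net, model$params, x, training = FALSE)
  softmax_prob(fwd$out)
}

#' @export
print.seg_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<seg_model: %s>\n", cfg$arch))
  cat(sprintf("  input %d x %d x %d, depth %d, base width %d\n",
              cfg$input_size, cfg$input_size, cfg$in_channels, cfg$depth,
              cfg$base_width))
  cat(sprintf("  trainable parameters: %s\n",
              format(x$parameter_count, big.mark = ",")))
  cat(sprintf("  weights: %s\n",
              if (is.null(x$params)) "uninitialized" else "present"))
  invisible(x)
}
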