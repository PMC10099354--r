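#' Train/validation/test split specification
#'
#' The patch set is split by a seeded uniform shuffle followed by a
#' contiguous 70/10/20 cut; train and validation sizes are
#' `floor(n * frac)` and the remainder goes to test, so the three parts
#' are always disjoint and exhaustive.
#'
#' @param train_frac,val_frac,test_frac Fractions summing to 1
#'   (defaults 0.70 / 0.10 / 0.20).
#' @param seed Shuffle seed.
#' @return A `split_spec`.
#' @export
split_spec <- function(train_frac = 0.70, val_frac = 0.10, test_frac = 0.20,
                       seed = 1L) {
  if (abs(train_frac + val_frac + test_frac - 1) > 1e-9)
    stop("split fractions must sum to 1 (got ",
         train_frac + val_frac + test_frac, ")")
  structure(list(train_frac = train_frac, val_frac = val_frac,
                 test_frac = test_frac, seed = as.integer(seed)),
            class = "split_spec")
}

#' Split a patch set into train/validation/test
#'
#' @param patches A list (or vector) of patches.
#' @param spec A [split_spec()].
#' @return List with elements `train`, `val`, `test` (subsets of
#'   `patches`) and an `indices` attribute recording the permutation.
#' @export
split_patches <- function(patches, spec = split_spec()) {
  n <- length(patches)
  if (n < 10) stop("need at least 10 patches to split, got ", n)
  n_train <- floor(n * spec$train_frac)
  n_val <- floor(n * spec$val_frac)
  perm <- withr::with_seed(spec$seed, sample.int(n))
  idx <- list(train = perm[seq_len(n_train)],
              val = perm[n_train + seq_len(n_val)],
              test = perm[(n_train + n_val + 1):n])
  out <- lapply(idx, function(i) patches[i])
  attr(out, "indices") <- idx
  out
}

#' Cut paired image/mask patches from whole synthetic samples
#'
#' Applies the overlapping sliding-window plan to every sample, discards
#' all-black image windows (as in training-set construction), and cuts the
#' ground-truth mask with the same grid so image and mask patches are
#' aligned by construction.
#'
#' @param samples List of `synth_sample` objects (or lists with `image`
#'   and `mask`).
#' @param config A [tiling_config()].
#' @return List of `list(x = patch array, y = mask matrix)` pairs.
#' @export
make_patch_dataset <- function(samples, config = tiling_config()) {
  out <- list()
  for (s in samples) {
    plan <- compute_grid(dim(s$image)[1:2], config)
    rois <- extract_rois(s$image, plan, config)
    w <- config$window
    for (r in rois) {
      y <- s$mask[r$row + seq_len(w), r$col + seq_len(w)]
      out[[length(out) + 1L]] <- list(x = r$patch, y = y,
                                      row = r$row, col = r$col)
    }
  }
  out
}

#' Training configuration
#'
#' Patch-level training uses the Adam optimizer and the two-class softmax
#' cross-entropy (equivalent to binary cross entropy on the foreground
#' probability). The run is fully seeded: shuffling, batching and weight
#' initialization all derive from `seed`.
#'
#' @param lr Adam learning rate.
#' @param epochs Number of passes over the training patches.
#' @param batch_size Patches per optimizer step.
#' @param seed RNG seed for shuffling (weights use the model seed).
#' @return A `train_config`.
#' @export
train_config <- function(lr = 1e-3, epochs = 3L, batch_size = 8L, seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, lr > 0)
  structure(list(lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "train_config")
}

# stack a list of (H,W,3) patches / (H,W) masks along a new last axis
.stack_x <- function(patches) {
  d <- dim(patches[[1]])
  array(unlist(patches, use.names = FALSE), c(d, length(patches)))
}
.stack_y <- function(masks) {
  d <- dim(masks[[1]])
  array(unlist(masks, use.names = FALSE) != 0, c(d, length(masks)))
}

# pooled Dice over a patch set (confusion counts summed across patches)
.pooled_dice <- function(model, patches, tau = 0.5, batch_size = 8L) {
  tp <- 0; fp <- 0; fn <- 0
  i <- 1L
  while (i <= length(patches)) {
    j <- min(i + batch_size - 1L, length(patches))
    x <- .stack_x(lapply(patches[i:j], `[[`, "x"))
    y <- .stack_y(lapply(patches[i:j], `[[`, "y"))
    p <- predict_patch_batch(model, x) > tau
    tp <- tp + sum(p & y)
    fp <- fp + sum(p & !y)
    fn <- fn + sum(!p & y)
    i <- j + 1L
  }
  denom <- 2 * tp + fp + fn
  if (denom == 0) 1 else 2 * tp / denom
}

#' Train a segmentation model on patch pairs
#'
#' Runs seeded minibatch Adam on the two-class cross-entropy loss and
#' returns the weights of the epoch with the best validation Dice
#' (pooled over validation patches). Per-epoch loss, mean predicted
#' foreground probability and validation Dice are kept in the returned
#' model's `history`.
#'
#' @param model A `seg_model` (weights are initialized from the model seed
#'   if absent).
#' @param train List of `list(x, y)` training patch pairs.
#' @param val List of `list(x, y)` validation pairs (may be empty; the
#'   final epoch is then kept).
#' @param config A [train_config()].
#' @return The trained `seg_model` with `history` (data frame) attached.
#' @export
train_model <- function(model, train, val = list(), config = train_config()) {
  stopifnot(inherits(model, "seg_model"))
  if (!length(train)) stop("training set is empty")
  if (is.null(model$params))
    model$params <- net_init_params(model$net, seed = model$config$seed)
  params <- model$params
  tn <- net_trainable_names(model$net) # frozen params are already excluded
  state <- adam_init(params, tn)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        mean_fg_prob = numeric(), val_dice = numeric())
  best <- list(dice = -Inf, params = params)
  withr::with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(length(train))
      losses <- numeric(); fgp <- numeric()
      i <- 1L
      while (i <= length(ord)) {
        j <- min(i + config$batch_size - 1L, length(ord))
        sel <- ord[i:j]
        x <- .stack_x(lapply(train[sel], `[[`, "x"))
        y <- .stack_y(lapply(train[sel], `[[`, "y"))
        fwd <- net_forward(model$net, params, x, training = TRUE)
        for (nm in names(fwd$bn_updates)) params[[nm]] <- fwd$bn_updates[[nm]]
        l <- softmax_ce(fwd$out, y)
        grads <- net_backward(model$net, params, fwd, l$dlogits)
        upd <- adam_step(params, grads, state, lr = config$lr)
        params <- upd$params
        state <- upd$state
        losses <- c(losses, l$loss)
        fgp <- c(fgp, mean(l$p_fg))
        i <- j + 1L
      }
      model$params <- params
      vd <- if (length(val)) .pooled_dice(model, val,
                                          batch_size = config$batch_size)
            else NA_real_
      history[nrow(history) + 1L, ] <- list(epoch, mean(losses), mean(fgp), vd)
      if (!length(val) || vd >= best$dice) {
        best$dice <- if (length(val)) vd else epoch
        best$params <- params
      }
    }
  })
  model$params <- best$params
  model$history <- history
  model$trained <- TRUE
  model
}
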