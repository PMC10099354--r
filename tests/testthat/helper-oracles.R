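# Independent oracles used across the suite. These are deliberately naive
# (double loops, flood fill, direct convolution) so they share no code with
# the implementation they check.

# 4-connected component labelling by flood fill
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  h <- nrow(mask); w <- ncol(mask)
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j))
    lab[i, j] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        q <- p + d
        if (q[1] >= 1 && q[1] <= h && q[2] >= 1 && q[2] <= w &&
            mask[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
          lab[q[1], q[2]] <- cur
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
  }
  lab
}

# brute-force pixel-by-pixel confusion counts
brute_confusion <- function(gt, s) {
  tp <- 0L; fp <- 0L; fn <- 0L
  for (j in seq_len(ncol(gt))) for (i in seq_len(nrow(gt))) {
    if (gt[i, j] && s[i, j]) tp <- tp + 1L
    else if (!gt[i, j] && s[i, j]) fp <- fp + 1L
    else if (gt[i, j] && !s[i, j]) fn <- fn + 1L
  }
  list(tp = tp, fp = fp, fn = fn)
}

# direct (quadruple-loop) 2-d convolution oracle, zero padding
conv_oracle <- function(x, Wm, b, k, stride, pad) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  Ho <- (H + 2 * pad - k) %/% stride + 1
  Wo <- (W + 2 * pad - k) %/% stride + 1
  cout <- ncol(Wm)
  out <- array(0, c(Ho, Wo, cout, N))
  for (n in seq_len(N)) for (o in seq_len(cout)) {
    for (wo in seq_len(Wo)) for (ho in seq_len(Ho)) {
      acc <- b[o]
      for (c in seq_len(C)) for (dj in seq_len(k)) for (di in seq_len(k)) {
        hh <- (ho - 1) * stride - pad + di
        ww <- (wo - 1) * stride - pad + dj
        if (hh >= 1 && hh <= H && ww >= 1 && ww <= W) {
          wi <- (di - 1) + k * (dj - 1) + k * k * (c - 1) + 1
          acc <- acc + x[hh, ww, c, n] * Wm[wi, o]
        }
      }
      out[ho, wo, o, n] <- acc
    }
  }
  out
}

# random reddish patch and sparse mask used by training smoke tests
random_patch_pair <- function(size = 32L, fg = FALSE) {
  x <- array(runif(size * size * 3, 0.3, 0.8), c(size, size, 3))
  y <- if (fg) matrix(runif(size * size) > 0.9, size, size)
       else matrix(FALSE, size, size)
  list(x = x, y = y)
}

# tiny U-Net configuration used wherever a real (but fast) model is needed
tiny_unet <- function(seed = 3L, input = 32L) {
  build_unet(model_config("unet", input_size = input, base_width = 4L,
                          depth = 2L, bottleneck_width = 16L, seed = seed))
}
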