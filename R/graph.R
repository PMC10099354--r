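# Minimal computational-graph engine for encoder-decoder segmentation nets.
#
# A network is a topologically ordered list of ops (each op's inputs have
# smaller ids). Tensors are (H, W, C, N) double arrays. Convolution weights
# live in a flat named list of parameter arrays so the optimizer can treat
# the model as a single vector of leaves. Heavy kernels (convolution,
# transposed convolution, pooling, upsampling) are in compiled code.

`%||%` <- function(a, b) if (is.null(a)) b else a

new_graph <- function() {
  env <- new.env(parent = emptyenv())
  env$ops <- list()
  env
}

g_add <- function(g, type, inputs = integer(), attrs = list(),
                  par_shapes = list(), trainable = logical()) {
  force(inputs) # nested builder calls must register before we take an id
  id <- length(g$ops) + 1L
  stopifnot(all(inputs < id))
  g$ops[[id]] <- list(id = id, type = type, inputs = as.integer(inputs),
                      attrs = attrs, par_shapes = par_shapes,
                      trainable = trainable)
  id
}

g_input  <- function(g, channels) {
  g_add(g, "input", attrs = list(channels = channels))
}

g_conv <- function(g, x, cin, cout, k = 3L, stride = 1L,
                   pad = (k - 1L) %/% 2L, bias_init = 0, w_sd = NULL) {
  g_add(g, "conv", x, attrs = list(k = k, stride = stride, pad = pad,
                                   cin = cin, cout = cout, channels = cout,
                                   bias_init = bias_init, w_sd = w_sd),
        par_shapes = list(W = c(k * k * cin, cout), b = cout),
        trainable = c(W = TRUE, b = TRUE))
}

g_upconv2 <- function(g, x, cin, cout) {
  g_add(g, "upconv2", x, attrs = list(cin = cin, cout = cout, channels = cout),
        par_shapes = list(W = c(4L * cin, cout), b = cout),
        trainable = c(W = TRUE, b = TRUE))
}

g_bn <- function(g, x, channels, momentum = 0.1, eps = 1e-5,
                 gamma_init = 1) {
  g_add(g, "bn", x, attrs = list(channels = channels, momentum = momentum,
                                 eps = eps, gamma_init = gamma_init),
        par_shapes = list(gamma = channels, beta = channels,
                          rmean = channels, rvar = channels),
        trainable = c(gamma = TRUE, beta = TRUE, rmean = FALSE, rvar = FALSE))
}

g_relu    <- function(g, x, channels) g_add(g, "relu", x, attrs = list(channels = channels))
g_sigmoid <- function(g, x, channels) g_add(g, "sigmoid", x, attrs = list(channels = channels))
g_pool    <- function(g, x, channels, k = 2L, stride = 2L, pad = 0L) {
  g_add(g, "pool", x, attrs = list(k = k, stride = stride, pad = pad,
                                   channels = channels))
}
g_up2 <- function(g, x, channels) g_add(g, "up2", x, attrs = list(channels = channels))

g_concat <- function(g, xs, channels_each) {
  g_add(g, "concat", xs, attrs = list(splits = as.integer(channels_each),
                                      channels = sum(channels_each)))
}
g_addop <- function(g, a, b, channels) g_add(g, "add", c(a, b), attrs = list(channels = channels))
# y = x * att, att has a single channel broadcast over x's channels
g_scale <- function(g, x, att, channels) {
  g_add(g, "scale", c(x, att), attrs = list(channels = channels))
}
# elementwise mean of k same-shaped inputs (deep-supervision head averaging)
g_mean <- function(g, xs, channels) {
  g_add(g, "mean", xs, attrs = list(channels = channels))
}

op_par_names <- function(op) {
  if (!length(op$par_shapes)) return(character())
  sprintf("op%04d.%s", op$id, names(op$par_shapes))
}

#' @noRd
net_param_count <- function(net) {
  total <- 0
  for (op in net$ops) {
    if (!length(op$par_shapes)) next
    for (nm in names(op$par_shapes)) {
      if (isTRUE(op$trainable[[nm]]))
        total <- total + prod(op$par_shapes[[nm]])
    }
  }
  total
}

# He-normal initialization for convolution weights, identity for batch norm.
net_init_params <- function(net, seed = 42L) {
  params <- list()
  withr::with_seed(as.integer(seed), {
    for (op in net$ops) {
      if (!length(op$par_shapes)) next
      nms <- op_par_names(op)
      for (i in seq_along(op$par_shapes)) {
        nm  <- names(op$par_shapes)[i]
        shp <- op$par_shapes[[i]]
        val <- switch(paste(op$type, nm, sep = "."),
          "conv.W"    = matrix(stats::rnorm(prod(shp),
                                            sd = op$attrs$w_sd %||%
                                              sqrt(2 / shp[1])),
                               shp[1], shp[2]),
          "upconv2.W" = matrix(stats::rnorm(prod(shp), sd = sqrt(2 / shp[1])),
                               shp[1], shp[2]),
          "conv.b"    = rep(op$attrs$bias_init %||% 0, shp),
          "upconv2.b" = numeric(shp),
          "bn.gamma"  = rep(op$attrs$gamma_init %||% 1, shp),
          "bn.beta"   = numeric(shp),
          "bn.rmean"  = numeric(shp),
          "bn.rvar"   = rep(1, shp),
          stop("unknown parameter ", nm, " for op type ", op$type))
        params[[nms[i]]] <- val
      }
    }
  })
  params
}

# Forward pass. Returns output tensor, all intermediate values (needed for
# backward), per-op caches, and updated batch-norm running statistics.
net_forward <- function(net, params, x, training = FALSE) {
  n <- length(net$ops)
  vals <- vector("list", n)
  caches <- vector("list", n)
  bn_updates <- list()
  for (op in net$ops) {
    id <- op$id
    vals[[id]] <- switch(op$type,
      input = x,
      conv = {
        xin <- vals[[op$inputs]]
        .conv_fwd(xin, params[[sprintf("op%04d.W", id)]],
                  params[[sprintf("op%04d.b", id)]],
                  op$attrs$k, op$attrs$stride, op$attrs$pad)
      },
      upconv2 = {
        .upconv2_fwd(vals[[op$inputs]], params[[sprintf("op%04d.W", id)]],
                     params[[sprintf("op%04d.b", id)]])
      },
      bn = {
        xin <- vals[[op$inputs]]
        r <- .bn_fwd(xin, params[[sprintf("op%04d.gamma", id)]],
                     params[[sprintf("op%04d.beta", id)]],
                     params[[sprintf("op%04d.rmean", id)]],
                     params[[sprintf("op%04d.rvar", id)]],
                     op$attrs$eps, training)
        if (training) {
          caches[[id]] <- list(mu = r$mu, ivar = r$ivar)
          mom <- op$attrs$momentum
          v <- 1 / r$ivar^2 - op$attrs$eps
          bn_updates[[sprintf("op%04d.rmean", id)]] <-
            (1 - mom) * params[[sprintf("op%04d.rmean", id)]] + mom * r$mu
          bn_updates[[sprintf("op%04d.rvar", id)]] <-
            (1 - mom) * params[[sprintf("op%04d.rvar", id)]] + mom * v
        }
        r$out
      },
      relu = {
        xin <- vals[[op$inputs]]
        xin * (xin > 0)
      },
      sigmoid = 1 / (1 + exp(-vals[[op$inputs]])),
      pool = {
        r <- .maxpool_fwd(vals[[op$inputs]], op$attrs$k, op$attrs$stride,
                          op$attrs$pad)
        caches[[id]] <- list(argmax = r$argmax, xdim = dim(vals[[op$inputs]]))
        r$out
      },
      up2 = .up2_fwd(vals[[op$inputs]]),
      concat = {
        ins <- lapply(op$inputs, function(i) vals[[i]])
        d1 <- dim(ins[[1]])
        ctot <- sum(vapply(ins, function(a) dim(a)[3], numeric(1)))
        out <- array(0, c(d1[1], d1[2], ctot, d1[4]))
        at <- 0L
        for (a in ins) {
          ca <- dim(a)[3]
          out[, , at + seq_len(ca), ] <- a
          at <- at + ca
        }
        out
      },
      add = vals[[op$inputs[1]]] + vals[[op$inputs[2]]],
      mean = {
        s <- vals[[op$inputs[1]]]
        for (i in op$inputs[-1]) s <- s + vals[[i]]
        s / length(op$inputs)
      },
      scale = {
        xin <- vals[[op$inputs[1]]]
        att <- vals[[op$inputs[2]]]
        C <- dim(xin)[3]
        xin * array(att[, , rep(1L, C), , drop = FALSE], dim(xin))
      },
      stop("unknown op type ", op$type))
  }
  list(out = vals[[length(net$ops)]], vals = vals, caches = caches,
       bn_updates = bn_updates)
}

# Reverse-mode gradients. `dout` is the gradient of the scalar loss with
# respect to the network output; returns gradients for every trainable
# parameter (named as in `params`).
net_backward <- function(net, params, fwd, dout) {
  n <- length(net$ops)
  gvals <- vector("list", n)
  gvals[[n]] <- dout
  pgrads <- list()
  acc <- function(slot, g) {
    if (is.null(gvals[[slot]])) gvals[[slot]] <<- g
    else gvals[[slot]] <<- gvals[[slot]] + g
  }
  for (id in rev(seq_len(n))) {
    op <- net$ops[[id]]
    g <- gvals[[id]]
    if (is.null(g)) next
    switch(op$type,
      input = NULL,
      conv = {
        xin <- fwd$vals[[op$inputs]]
        r <- .conv_bwd(xin, params[[sprintf("op%04d.W", id)]], g,
                       op$attrs$k, op$attrs$stride, op$attrs$pad)
        pgrads[[sprintf("op%04d.W", id)]] <- r$dW
        pgrads[[sprintf("op%04d.b", id)]] <- as.numeric(r$db)
        acc(op$inputs, r$dx)
      },
      upconv2 = {
        xin <- fwd$vals[[op$inputs]]
        r <- .upconv2_bwd(xin, params[[sprintf("op%04d.W", id)]], g)
        pgrads[[sprintf("op%04d.W", id)]] <- r$dW
        pgrads[[sprintf("op%04d.b", id)]] <- as.numeric(r$db)
        acc(op$inputs, r$dx)
      },
      bn = {
        cache <- fwd$caches[[id]]
        if (is.null(cache))
          stop("batch-norm backward requires a training-mode forward pass")
        r <- .bn_bwd(fwd$vals[[op$inputs]],
                     params[[sprintf("op%04d.gamma", id)]],
                     cache$mu, cache$ivar, g)
        pgrads[[sprintf("op%04d.gamma", id)]] <- r$dgamma
        pgrads[[sprintf("op%04d.beta", id)]]  <- r$dbeta
        acc(op$inputs, r$dx)
      },
      relu = {
        xin <- fwd$vals[[op$inputs]]
        acc(op$inputs, g * (xin > 0))
      },
      sigmoid = {
        s <- fwd$vals[[id]]
        acc(op$inputs, g * s * (1 - s))
      },
      pool = {
        cache <- fwd$caches[[id]]
        acc(op$inputs, .maxpool_bwd(g, cache$argmax, as.integer(cache$xdim)))
      },
      up2 = acc(op$inputs, .up2_bwd(g)),
      concat = {
        at <- 0L
        for (j in seq_along(op$inputs)) {
          ca <- op$attrs$splits[j]
          acc(op$inputs[j], g[, , at + seq_len(ca), , drop = FALSE])
          at <- at + ca
        }
      },
      add = {
        acc(op$inputs[1], g)
        acc(op$inputs[2], g)
      },
      mean = {
        gk <- g / length(op$inputs)
        for (i in op$inputs) acc(i, gk)
      },
      scale = {
        xin <- fwd$vals[[op$inputs[1]]]
        att <- fwd$vals[[op$inputs[2]]]
        C <- dim(xin)[3]
        attr_rep <- array(att[, , rep(1L, C), , drop = FALSE], dim(xin))
        acc(op$inputs[1], g * attr_rep)
        datt <- apply(g * xin, c(1, 2, 4), sum)
        acc(op$inputs[2], array(datt, dim(att)))
      },
      stop("unknown op type ", op$type))
    gvals[[id]] <- NULL # free memory as we go
  }
  pgrads
}

# Two-class softmax cross-entropy on logits (H, W, 2, N) against a binary
# target (H, W, N). Returns the mean per-pixel loss and d loss / d logits.
softmax_ce <- function(logits, target) {
  d <- dim(logits)
  stopifnot(d[3] == 2)
  z_bg <- logits[, , 1L, , drop = FALSE]
  z_fg <- logits[, , 2L, , drop = FALSE]
  zm <- pmax(z_bg, z_fg)
  lse <- zm + log(exp(z_bg - zm) + exp(z_fg - zm))
  y <- array(as.numeric(target), dim(z_fg))
  logp <- y * (z_fg - lse) + (1 - y) * (z_bg - lse)
  M <- length(logp)
  p_fg <- exp(z_fg - lse)
  dz_fg <- (p_fg - y) / M
  dlogits <- array(0, d)
  dlogits[, , 1L, ] <- -dz_fg
  dlogits[, , 2L, ] <- dz_fg
  list(loss = -sum(logp) / M, dlogits = dlogits,
       p_fg = array(p_fg, d[c(1, 2, 4)]))
}

# foreground probability from 2-channel logits, inference mode
softmax_prob <- function(logits) {
  z_bg <- logits[, , 1L, , drop = FALSE]
  z_fg <- logits[, , 2L, , drop = FALSE]
  p <- 1 / (1 + exp(z_bg - z_fg))
  array(p, dim(logits)[c(1, 2, 4)])
}

# Adam optimizer state and update step
adam_init <- function(params, trainable_names) {
  list(m = lapply(params[trainable_names], function(p) p * 0),
       v = lapply(params[trainable_names], function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(state$m)) {
    gr <- grads[[nm]]
    if (is.null(gr)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr * gr
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

net_trainable_names <- function(net) {
  out <- character()
  for (op in net$ops) {
    if (!length(op$par_shapes)) next
    nms <- op_par_names(op)
    keep <- vapply(names(op$par_shapes), function(nm) isTRUE(op$trainable[[nm]]),
                   logical(1))
    out <- c(out, nms[keep])
  }
  out
}
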