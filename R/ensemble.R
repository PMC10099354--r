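#' Ensemble of the three segmentation models
#'
#' Combines a U-Net, a ResNet34-UNet and a U-Net++ into one predictor.
#' The default combiner is the pixelwise arithmetic mean of the member
#' probability maps, taken before thresholding; majority voting (pixel
#' foreground if at least two members exceed the threshold, expressed as
#' a 0/1-valued probability map) is available for comparison.
#'
#' @param unet,resnet34_unet,unetpp The three trained `seg_model` members.
#' @param combine `"mean"` (default) or `"vote"`.
#' @return A `seg_ensemble`.
#' @export
seg_ensemble <- function(unet, resnet34_unet, unetpp,
                         combine = c("mean", "vote")) {
  combine <- match.arg(combine)
  members <- list(unet = unet, resnet34_unet = resnet34_unet,
                  unetpp = unetpp)
  for (nm in names(members)) {
    m <- members[[nm]]
    if (!inherits(m, "seg_model"))
      stop("member '", nm, "' is not a seg_model")
    if (m$config$arch != nm)
      stop("member '", nm, "' was built as '", m$config$arch, "'")
  }
  structure(list(members = members, combine = combine),
            class = "seg_ensemble")
}

#' @export
print.seg_ensemble <- function(x, ...) {
  cat("<seg_ensemble of U-Net, ResNet34-UNet, U-Net++; combine =",
      x$combine, ">\n")
  invisible(x)
}

#' Ensemble prediction for one patch
#'
#' Pixelwise mean of the three member probability maps (or a majority
#' vote). With identical members the ensemble output equals any member's
#' output, and the mean never leaves the min-max envelope of the members.
#'
#' @param ensemble A [seg_ensemble()].
#' @param patch Numeric array `H x W x 3` in `[0, 1]`.
#' @return Matrix of probabilities.
#' @export
ensemble_predict_patch <- function(ensemble, patch) {
  p <- predict_patch_batch(ensemble, array(patch, c(dim(patch)[1:2],
                                                    dim(patch)[3], 1L)))
  p[, , 1L]
}

#' @export
predict_patch_batch.seg_ensemble <- function(model, x) {
  probs <- lapply(model$members, predict_patch_batch, x = x)
  d <- dim(probs[[1]])
  for (p in probs[-1]) {
    if (!all(dim(p) == d))
      stop("ensemble member output shapes disagree: ",
           paste(d, collapse = "x"), " vs ", paste(dim(p), collapse = "x"))
  }
  if (model$combine == "mean") {
    (probs[[1]] + probs[[2]] + probs[[3]]) / 3
  } else {
    votes <- (probs[[1]] > 0.5) + (probs[[2]] > 0.5) + (probs[[3]] > 0.5)
    array(as.numeric(votes >= 2), d)
  }
}

#' Segment a whole fundus image
#'
#' Whole-image prediction: break the image into the overlapping window
#' grid, predict every window (at inference no window is discarded, so
#' the canvas is fully covered), accumulate the patch probability maps,
#' divide by the per-pixel overlap count, and threshold. Returns both the
#' continuous probability map and the binary segmentation mask.
#'
#' @param image Numeric array `H x W x 3` in `[0, 1]`, at least
#'   window-sized on both axes.
#' @param predictor A `seg_model`, a [seg_ensemble()], or a plain function
#'   mapping an `H x W x C x N` patch batch to an `H x W x N` probability
#'   array (handy for diagnostics with stub predictors).
#' @param config A [tiling_config()].
#' @param tau Decision threshold (default 0.5; strictly greater than).
#' @param batch_size Windows predicted per forward pass.
#' @return List with `prob_map` (matrix in `[0, 1]`) and `mask` (logical
#'   matrix, TRUE = microaneurysm).
#' @export
predict_image <- function(image, predictor, config = tiling_config(),
                          tau = 0.5, batch_size = 8L) {
  d <- dim(image)
  plan <- compute_grid(d[1:2], config)
  canvas <- probability_canvas(d[1:2])
  w <- config$window
  n <- nrow(plan$origins)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    idx <- i:j
    x <- array(0, c(w, w, d[3], length(idx)))
    for (kk in seq_along(idx)) {
      r <- plan$origins$row[idx[kk]]
      cc <- plan$origins$col[idx[kk]]
      x[, , , kk] <- image[r + seq_len(w), cc + seq_len(w), ]
    }
    p <- if (is.function(predictor)) predictor(x)
         else predict_patch_batch(predictor, x)
    for (kk in seq_along(idx)) {
      canvas <- accumulate_patch(canvas,
                                 c(plan$origins$row[idx[kk]],
                                   plan$origins$col[idx[kk]]),
                                 p[, , kk])
    }
    i <- j + 1L
  }
  prob_map <- finalize_map(canvas)
  list(prob_map = prob_map, mask = threshold_map(prob_map, tau))
}
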