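#' Tiling configuration
#'
#' Parameters of the overlapping sliding-window scheme used to break a
#' whole fundus image into fixed-size square patches (regions of interest)
#' and to reconstruct the whole-image probability map afterwards.
#'
#' The stride between window origins is `floor(window * (1 - overlap))`,
#' so the requested overlap is a lower bound and the stride is integral.
#'
#' @param window Patch side length in pixels (default 576).
#' @param overlap Fraction of window overlap between neighbouring patches,
#'   in `[0, 1)` (default 0.30).
#' @param black_tol Maximum 8-bit intensity still counted as "black" when
#'   discarding all-black training patches (default 0, i.e. strictly black).
#' @return A `tiling_config` object.
#' @export
tiling_config <- function(window = 576L, overlap = 0.30, black_tol = 0L) {
  window <- as.integer(window)
  stopifnot(window > 0, overlap >= 0, overlap < 1,
            black_tol >= 0, black_tol <= 255)
  stride <- as.integer(floor(window * (1 - overlap)))
  if (stride < 1) stop("overlap too large: stride would be < 1 pixel")
  structure(list(window = window, overlap = overlap,
                 black_tol = as.integer(black_tol), stride = stride),
            class = "tiling_config")
}

# origins along one axis: 0, s, 2s, ... plus an edge-anchored final origin
.axis_origins <- function(size, window, stride) {
  last <- size - window
  org <- seq.int(0L, last, by = stride)
  if (org[length(org)] != last) org <- c(org, as.integer(last))
  as.integer(org)
}

#' Plan the overlapping sliding-window grid
#'
#' Computes the top-left corners (0-based, row-major, half-open windows
#' `[r, r + window) x [c, c + window)`) of every patch. Per axis the
#' origins are `0, s, 2s, ...` with stride `s = floor(window * (1 -
#' overlap))`; if the last regular origin does not bring the window flush
#' with the image edge, one extra origin anchored at `size - window` is
#' appended, so the plan always covers every pixel.
#'
#' @param image_size Integer `(height, width)` in pixels.
#' @param config A [tiling_config()].
#' @return A `tiling_plan`: list with `image_size`, `window`, and
#'   `origins`, a data frame with 0-based `row`/`col` columns, one row per
#'   patch in row-major order.
#' @export
compute_grid <- function(image_size, config = tiling_config()) {
  image_size <- as.integer(image_size)
  stopifnot(length(image_size) == 2)
  w <- config$window
  if (any(image_size < w))
    stop("image (", image_size[1], " x ", image_size[2],
         ") is smaller than the ", w, "-pixel window; pad the image or ",
         "use a smaller window")
  rows <- .axis_origins(image_size[1], w, config$stride)
  cols <- .axis_origins(image_size[2], w, config$stride)
  origins <- expand.grid(col = cols, row = rows,
                         KEEP.OUT.ATTRS = FALSE)[, c("row", "col")]
  rownames(origins) <- NULL
  structure(list(image_size = image_size, window = w, origins = origins),
            class = "tiling_plan")
}

#' @export
print.tiling_plan <- function(x, ...) {
  cat(sprintf("<tiling_plan: %d patches of %d px over %d x %d image>\n",
              nrow(x$origins), x$window, x$image_size[1], x$image_size[2]))
  invisible(x)
}

# is every pixel of this window at most `tol` (8-bit) in every channel?
.is_black_patch <- function(patch, tol) {
  all(round(patch * 255) <= tol)
}

#' Extract overlapping patches, discarding all-black ones
#'
#' Crops every window of the plan from the image and drops the windows
#' whose pixels are all black (every channel at most `black_tol` in 8-bit
#' units), as done when building the training patch set. The manifest
#' records every window with its discard flag; the number of discarded
#' windows is also attached as an attribute.
#'
#' @param image Numeric array `H x W x 3` with values in `[0, 1]`.
#' @param plan A [compute_grid()] plan matching the image size.
#' @param config The [tiling_config()] used for `black_tol`.
#' @return List of `list(row, col, patch)` entries (0-based origins), with
#'   attributes `manifest` (data frame: `row`, `col`, `window`,
#'   `discarded`) and `n_discarded`.
#' @export
extract_rois <- function(image, plan, config = tiling_config()) {
  stopifnot(inherits(plan, "tiling_plan"))
  d <- dim(image)
  if (!all(d[1:2] == plan$image_size))
    stop("plan was computed for a ", plan$image_size[1], " x ",
         plan$image_size[2], " image but got ", d[1], " x ", d[2])
  w <- plan$window
  out <- vector("list", nrow(plan$origins))
  discarded <- logical(nrow(plan$origins))
  kept <- 0L
  for (i in seq_len(nrow(plan$origins))) {
    r <- plan$origins$row[i]
    cc <- plan$origins$col[i]
    patch <- image[r + seq_len(w), cc + seq_len(w), , drop = FALSE]
    if (.is_black_patch(patch, config$black_tol)) {
      discarded[i] <- TRUE
    } else {
      kept <- kept + 1L
      out[[kept]] <- list(row = r, col = cc, patch = patch)
    }
  }
  out <- out[seq_len(kept)]
  attr(out, "manifest") <- data.frame(row = plan$origins$row,
                                      col = plan$origins$col,
                                      window = w, discarded = discarded)
  attr(out, "n_discarded") <- sum(discarded)
  out
}

#' Create an empty probability canvas
#'
#' The canvas accumulates per-pixel predicted probabilities (`prob_sum`)
#' and the number of windows covering each pixel (`count`), so that
#' overlapping patch predictions can be averaged during reconstruction.
#'
#' @param image_size Integer `(height, width)`.
#' @return A `probability_canvas`.
#' @export
probability_canvas <- function(image_size) {
  image_size <- as.integer(image_size)
  structure(list(prob_sum = matrix(0, image_size[1], image_size[2]),
                 count = matrix(0L, image_size[1], image_size[2])),
            class = "probability_canvas")
}

#' Accumulate one patch prediction onto the canvas
#'
#' Adds the patch probabilities to `prob_sum` and increments `count` on
#' the covered window, exactly where the patch was cropped. Accumulation
#' order does not affect the final canvas.
#'
#' @param canvas A [probability_canvas()].
#' @param origin 0-based `(row, col)` top-left corner of the patch.
#' @param patch_probs Square matrix of probabilities in `[0, 1]`.
#' @return The updated canvas.
#' @export
accumulate_patch <- function(canvas, origin, patch_probs) {
  stopifnot(inherits(canvas, "probability_canvas"))
  w <- nrow(patch_probs)
  r <- as.integer(origin[1]); cc <- as.integer(origin[2])
  if (r < 0 || cc < 0 || r + w > nrow(canvas$prob_sum) ||
      cc + w > ncol(canvas$prob_sum))
    stop("patch at origin (", r, ", ", cc, ") does not fit on the canvas")
  if (any(patch_probs < 0) || any(patch_probs > 1))
    stop("patch probabilities must lie in [0, 1]")
  ri <- r + seq_len(w); ci <- cc + seq_len(w)
  canvas$prob_sum[ri, ci] <- canvas$prob_sum[ri, ci] + patch_probs
  canvas$count[ri, ci] <- canvas$count[ri, ci] + 1L
  canvas
}

#' Average the canvas into a whole-image probability map
#'
#' Divides the accumulated probability sum by the per-pixel overlap count.
#' Every pixel must be covered by at least one window (a covering plan
#' guarantees this).
#'
#' @param canvas A [probability_canvas()] after accumulation.
#' @return Matrix of per-pixel mean probabilities in `[0, 1]`.
#' @export
finalize_map <- function(canvas) {
  stopifnot(inherits(canvas, "probability_canvas"))
  if (any(canvas$count == 0L)) {
    bad <- which(canvas$count == 0L, arr.ind = TRUE)
    stop("canvas has ", nrow(bad), " uncovered pixel(s), e.g. row ",
         bad[1, 1], ", col ", bad[1, 2],
         " (1-based); accumulate a covering plan first")
  }
  canvas$prob_sum / canvas$count
}

#' Threshold a probability map into a segmentation mask
#'
#' Pixels with probability strictly greater than `tau` become
#' microaneurysm (TRUE); ties at exactly `tau` go to background.
#'
#' @param prob_map Matrix of probabilities in `[0, 1]`.
#' @param tau Threshold in `[0, 1]` (default 0.5).
#' @return Logical matrix, TRUE = microaneurysm.
#' @export
threshold_map <- function(prob_map, tau = 0.5) {
  if (tau < 0 || tau > 1) stop("tau must lie in [0, 1]")
  prob_map > tau
}
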