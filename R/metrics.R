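#' Pixel confusion counts between ground truth and a segmentation
#'
#' Pixel-set comparison of a predicted segmentation S against the ground
#' truth GT using logical set operations: TP = |GT AND S|,
#' FP = |(GT OR S) - GT| (pixels predicted outside the ground truth) and
#' FN = |(GT OR S) - S| (ground-truth pixels the model missed). True
#' negatives are not used by IoU or Dice.
#'
#' @param gt Logical matrix, TRUE = microaneurysm (ground truth).
#' @param s Logical matrix of the same shape (prediction).
#' @return A `metric_counts` list with integer fields `tp`, `fp`, `fn`.
#' @export
confusion_counts <- function(gt, s) {
  if (!all(dim(gt) == dim(s)))
    stop("ground truth (", paste(dim(gt), collapse = " x "),
         ") and segmentation (", paste(dim(s), collapse = " x "),
         ") have different shapes")
  gt <- as.logical(gt); s <- as.logical(s)
  structure(list(tp = sum(gt & s), fp = sum(s & !gt), fn = sum(gt & !s)),
            class = "metric_counts")
}

#' Intersection over union (Jaccard index)
#'
#' `TP / (TP + FP + FN)`: the ratio of the overlap area to the combined
#' area of prediction and ground truth; 0 means no overlap, 1 perfect
#' overlap. When both masks are empty (TP + FP + FN = 0) the value is
#' defined as 1 (perfect agreement on absence) and flagged via the
#' `degenerate` attribute.
#'
#' @param counts A [confusion_counts()] result.
#' @return IoU in `[0, 1]`.
#' @export
iou <- function(counts) {
  denom <- counts$tp + counts$fp + counts$fn
  if (denom == 0) return(structure(1, degenerate = TRUE))
  counts$tp / denom
}

#' Dice coefficient (F1 score)
#'
#' `2 TP / (2 TP + FP + FN)`; related to IoU by
#' `Dice = 2 IoU / (1 + IoU)`. The both-empty convention matches [iou()].
#'
#' @param counts A [confusion_counts()] result.
#' @return Dice in `[0, 1]`.
#' @export
dice <- function(counts) {
  denom <- 2 * counts$tp + counts$fp + counts$fn
  if (denom == 0) return(structure(1, degenerate = TRUE))
  2 * counts$tp / denom
}

#' Full metric report for one mask pair
#'
#' @param gt,s Logical masks of equal shape.
#' @return A `metric_report` list: `counts`, `iou`, `dice`, `degenerate`.
#' @export
metric_report <- function(gt, s) {
  counts <- confusion_counts(gt, s)
  i <- iou(counts); d <- dice(counts)
  structure(list(counts = counts, iou = as.numeric(i), dice = as.numeric(d),
                 degenerate = isTRUE(attr(i, "degenerate"))),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> TP %d  FP %d  FN %d  IoU %.4f  Dice %.4f%s\n",
              x$counts$tp, x$counts$fp, x$counts$fn, x$iou, x$dice,
              if (x$degenerate) "  (both masks empty)" else ""))
  invisible(x)
}

#' Evaluate paired prediction and ground-truth masks
#'
#' Computes per-image IoU and Dice and their unweighted means across
#' images, mirroring how per-image curves and averages are reported for a
#' test set.
#'
#' @param pred_masks List of logical prediction masks.
#' @param gt_masks List of logical ground-truth masks, same length and
#'   per-element shapes.
#' @return List with `per_image` (data frame: `image`, `tp`, `fp`, `fn`,
#'   `iou`, `dice`, `degenerate`), `mean_iou` and `mean_dice`.
#' @export
evaluate_masks <- function(pred_masks, gt_masks) {
  if (length(pred_masks) != length(gt_masks))
    stop("got ", length(pred_masks), " predictions but ",
         length(gt_masks), " ground-truth masks")
  reports <- Map(function(s, gt) metric_report(gt, s), pred_masks, gt_masks)
  per_image <- data.frame(
    image = seq_along(reports),
    tp = vapply(reports, function(r) r$counts$tp, numeric(1)),
    fp = vapply(reports, function(r) r$counts$fp, numeric(1)),
    fn = vapply(reports, function(r) r$counts$fn, numeric(1)),
    iou = vapply(reports, function(r) r$iou, numeric(1)),
    dice = vapply(reports, function(r) r$dice, numeric(1)),
    degenerate = vapply(reports, function(r) r$degenerate, logical(1)))
  list(per_image = per_image,
       mean_iou = mean(per_image$iou),
       mean_dice = mean(per_image$dice))
}
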