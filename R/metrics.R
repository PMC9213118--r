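#' Pixel-wise confusion counts between binary masks
#'
#' @param pred,label Binary ({0,1}) arrays of identical shape.
#' @return Named integer vector `c(tp, fp, fn, tn)`; the four counts sum to
#'   the total number of pixels.
#' @export
confusion_counts <- function(pred, label) {
  if (length(pred) != length(label))
    stop("shape error: masks differ in size")
  if (!all(pred %in% c(0, 1)) || !all(label %in% c(0, 1)))
    stop("confusion_counts expects binary {0,1} masks")
  tp <- sum(pred == 1 & label == 1)
  fp <- sum(pred == 1 & label == 0)
  fn <- sum(pred == 0 & label == 1)
  tn <- sum(pred == 0 & label == 0)
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

.check_counts <- function(...) {
  v <- c(...)
  if (any(v < 0)) stop("counts must be non-negative")
  v
}

#' Intersection over union (Jaccard index) from confusion counts
#'
#' `IoU = TP / (TP + FP + FN)`. When all three counts are zero (empty mask
#' versus empty mask) the value is defined as 1.
#'
#' @param tp,fp,fn Non-negative pixel counts.
#' @return A value in \[0, 1\].
#' @export
iou <- function(tp, fp, fn) {
  .check_counts(tp, fp, fn)
  den <- tp + fp + fn
  if (den == 0) return(1)
  tp / den
}

#' Dice similarity coefficient from confusion counts
#'
#' `Dice = 2 TP / (FP + 2 TP + FN)`; empty-versus-empty is defined as 1.
#' Algebraically `Dice = 2 IoU / (1 + IoU)`, so `IoU <= Dice <= 1`.
#'
#' @inheritParams iou
#' @return A value in \[0, 1\].
#' @export
dice <- function(tp, fp, fn) {
  .check_counts(tp, fp, fn)
  den <- fp + 2 * tp + fn
  if (den == 0) return(1)
  2 * tp / den
}

#' Bundle confusion counts with their IoU and Dice
#'
#' @param tp,fp,fn,tn Non-negative pixel counts.
#' @return A list of class `seg_metrics`.
#' @export
seg_metrics <- function(tp, fp, fn, tn) {
  .check_counts(tp, fp, fn, tn)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 iou = iou(tp, fp, fn), dice = dice(tp, fp, fn)),
            class = "seg_metrics")
}

#' @export
print.seg_metrics <- function(x, ...) {
  cat(sprintf("<seg_metrics> Dice %.4f  IoU %.4f  (tp %d fp %d fn %d tn %d)\n",
              x$dice, x$iou, x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Evaluate a model on a dataset
#'
#' Runs inference on every image, binarizes the probability map at
#' `threshold`, and aggregates pixel confusion counts. The micro average
#' pools counts over the whole set before computing Dice/IoU; the macro
#' average computes per-image Dice/IoU and averages those.
#'
#' @param model An [msfa_model()].
#' @param dataset A `seg_dataset` (see [load_split()]).
#' @param threshold Binarization threshold on the probability map.
#' @param average `"micro"` (default) or `"macro"`.
#' @param batch_size Images per forward pass.
#' @return For micro: a `seg_metrics`. For macro: a list with `dice`, `iou`
#'   and the per-image data.frame.
#' @export
evaluate_model <- function(model, dataset, threshold = 0.5,
                           average = c("micro", "macro"), batch_size = 8L) {
  average <- match.arg(average)
  n <- dim(dataset$images)[4]
  if (is.null(n) || n == 0) stop("empty dataset")
  counts <- c(tp = 0, fp = 0, fn = 0, tn = 0)
  per <- vector("list", n)
  for (i0 in seq(1, n, by = batch_size)) {
    idx <- i0:min(i0 + batch_size - 1, n)
    x <- dataset$images[, , , idx, drop = FALSE]
    y <- dataset$masks[, , , idx, drop = FALSE]
    fx <- msfa_forward(x, model, training = FALSE)
    bin <- (fx$prediction >= threshold) * 1
    for (k in seq_along(idx)) {
      cc <- confusion_counts(bin[, , , k], y[, , , k])
      counts <- counts + cc
      per[[idx[k]]] <- data.frame(
        image = idx[k], t(cc),
        dice = unname(dice(cc["tp"], cc["fp"], cc["fn"])),
        iou = unname(iou(cc["tp"], cc["fp"], cc["fn"])))
    }
  }
  if (average == "micro")
    return(seg_metrics(unname(counts["tp"]), unname(counts["fp"]),
                       unname(counts["fn"]), unname(counts["tn"])))
  per <- do.call(rbind, per)
  list(dice = mean(per$dice), iou = mean(per$iou), per_image = per)
}
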