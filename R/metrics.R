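#' Pixel accuracy
#'
#' Fraction of pixels whose predicted class equals the ground truth.
#'
#' @param pred,gt class-id (or binary) matrices of a common shape.
#' @return Scalar in \[0, 1\].
#' @export
pixel_accuracy <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt))) stop("pred and gt shapes differ")
  mean(pred == gt)
}

#' Intersection over union (Jaccard index)
#'
#' For binary masks (or a given `class_id`), `|A n B| / |A u B|`, with the
#' empty-over-empty convention IoU = 1. Without `class_id` on label masks the
#' micro-average is returned: summed intersections over summed unions across
#' the classes present in either mask.
#'
#' @param pred,gt masks of a common shape.
#' @param class_id optional class to score on label masks.
#' @return Scalar in \[0, 1\].
#' @export
iou <- function(pred, gt, class_id = NULL) {
  if (!identical(dim(pred), dim(gt))) stop("pred and gt shapes differ")
  if (!is.null(class_id)) {
    pred <- pred == class_id; gt <- gt == class_id
    inter <- sum(pred & gt); uni <- sum(pred | gt)
    return(if (uni == 0) 1 else inter / uni)
  }
  ids <- sort(unique(c(pred, gt)))
  if (all(ids %in% c(0, 1))) {                # binary masks: plain Jaccard
    inter <- sum(pred == 1 & gt == 1); uni <- sum(pred == 1 | gt == 1)
    return(if (uni == 0) 1 else inter / uni)
  }
  inter_tot <- 0; uni_tot <- 0                # label masks: micro-average
  for (k in ids) {
    inter_tot <- inter_tot + sum(pred == k & gt == k)
    uni_tot <- uni_tot + sum(pred == k | gt == k)
  }
  if (uni_tot == 0) 1 else inter_tot / uni_tot
}

#' Dice coefficient (F1 overlap)
#'
#' `2 |A n B| / (|A| + |B|)` with the 0/0 convention Dice = 1. Related to IoU
#' by `Dice = 2 IoU / (1 + IoU)` for any binary pair.
#'
#' @inheritParams iou
#' @return Scalar in \[0, 1\].
#' @export
dice_coefficient <- function(pred, gt, class_id = NULL) {
  if (!identical(dim(pred), dim(gt))) stop("pred and gt shapes differ")
  if (!is.null(class_id)) { pred <- pred == class_id; gt <- gt == class_id }
  else if (!(all(pred %in% c(0, 1)) && all(gt %in% c(0, 1)))) {
    j <- iou(pred, gt)
    return(2 * j / (1 + j))
  }
  inter <- sum(pred == 1 & gt == 1)
  tot <- sum(pred == 1) + sum(gt == 1)
  if (tot == 0) 1 else 2 * inter / tot
}

#' Mean intersection over union across classes
#'
#' Unweighted mean of per-class IoU over classes `0..K-1`; a class absent
#' from both masks contributes 1 by the empty-over-empty convention.
#'
#' @param pred,gt class-id matrices of a common shape.
#' @param K number of classes.
#' @return Scalar in \[0, 1\].
#' @export
mean_iou <- function(pred, gt, K = 6) {
  if (!identical(dim(pred), dim(gt))) stop("pred and gt shapes differ")
  if (any(pred >= K) || any(gt >= K)) stop("class id >= K")
  mean(vapply(0:(K - 1), function(k) iou(pred, gt, class_id = k), numeric(1)))
}
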