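# Segmentation and diagnosis evaluation: confusion counts, accuracy,
# sensitivity, specificity, Dice overlap, and ROC/AUC from a threshold sweep.

#' Confusion counts for a chosen positive class
#'
#' @param pred,truth [label_mask]s (or integer matrices/vectors) of identical
#'   shape.
#' @param positive_class the class treated as positive.
#' @return An object of class `confusion_counts`: list with integer `tp`,
#'   `tn`, `fp`, `fn`.
#' @export
confusion <- function(pred, truth, positive_class) {
  p <- if (inherits(pred, "label_mask")) mask_classes(pred) else pred
  t <- if (inherits(truth, "label_mask")) mask_classes(truth) else truth
  stop_if_shape_mismatch(dim(as.matrix(p)), dim(as.matrix(t)), "pred and truth")
  pp <- p == positive_class
  tt <- t == positive_class
  structure(list(tp = sum(pp & tt), tn = sum(!pp & !tt),
                 fp = sum(pp & !tt), fn = sum(!pp & tt)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion> tp=%d tn=%d fp=%d fn=%d\n", x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

total_counts <- function(c) c$tp + c$tn + c$fp + c$fn

#' Accuracy: (TP + TN) / total
#' @param c a `confusion_counts`.
#' @return Accuracy in \[0, 1\].
#' @export
accuracy <- function(c) {
  n <- total_counts(c)
  if (n < 1) stop("accuracy undefined on empty counts", call. = FALSE)
  (c$tp + c$tn) / n
}

#' Sensitivity (recall): TP / (TP + FN)
#' @param c a `confusion_counts`.
#' @return Sensitivity in \[0, 1\].
#' @export
sensitivity <- function(c) {
  if (c$tp + c$fn < 1) {
    stop("sensitivity undefined: no positive-class items", call. = FALSE)
  }
  c$tp / (c$tp + c$fn)
}

#' Specificity: TN / (FP + TN)
#' @param c a `confusion_counts`.
#' @return Specificity in \[0, 1\].
#' @export
specificity <- function(c) {
  if (c$tn + c$fp < 1) {
    stop("specificity undefined: no negative-class items", call. = FALSE)
  }
  c$tn / (c$fp + c$tn)
}

dice_one_class <- function(p, t, cls) {
  pi <- p == cls
  ti <- t == cls
  denom <- sum(pi) + sum(ti)
  if (denom == 0) return(1)  # both empty: perfect agreement on "nothing"
  2 * sum(pi & ti) / denom
}

#' Dice overlap coefficient
#'
#' Binary mode: `2|P∩L| / (|P| + |L|)` over the class-1 pixel sets of
#' two-class masks (empty vs empty is defined as 1.0). Macro mode: the
#' unweighted mean of the per-class binary Dice over every class present in
#' either mask.
#'
#' @param pred,truth [label_mask]s of identical shape.
#' @param mode `"binary"` or `"macro"`.
#' @return Dice value in \[0, 1\].
#' @export
dice <- function(pred, truth, mode = c("binary", "macro")) {
  mode <- match.arg(mode)
  p <- if (inherits(pred, "label_mask")) mask_classes(pred) else pred
  t <- if (inherits(truth, "label_mask")) mask_classes(truth) else truth
  stop_if_shape_mismatch(dim(as.matrix(p)), dim(as.matrix(t)), "pred and truth")
  if (mode == "binary") {
    if (inherits(pred, "label_mask") && mask_n_classes(pred) != 2L ||
        inherits(truth, "label_mask") && mask_n_classes(truth) != 2L) {
      stop("binary Dice requires two-class masks", call. = FALSE)
    }
    dice_one_class(p, t, 1L)
  } else {
    classes <- sort(union(unique(as.vector(p)), unique(as.vector(t))))
    mean(vapply(classes, function(cl) dice_one_class(p, t, cl), numeric(1)))
  }
}

#' ROC curve from a threshold sweep
#'
#' Sweeps the decision threshold over the unique score values (plus
#' sentinels): at each threshold items with score >= threshold are called
#' positive, giving TPR = sensitivity and FPR = 1 - specificity. The curve
#' starts at (0, 0) and ends at (1, 1) with non-decreasing FPR; tied scores
#' collapse to one threshold.
#'
#' @param scores numeric positive-class scores, one per item.
#' @param labels binary truth (0/1 or logical), both classes present.
#' @return A data.frame of class `roc_curve` with columns `threshold`,
#'   `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC requires at least one positive and one negative label",
         call. = FALSE)
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- t(vapply(thr, function(th) {
    called <- scores >= th
    c(fpr = sum(called & labels == 0L) / n_neg,
      tpr = sum(called & labels == 1L) / n_pos)
  }, numeric(2)))
  out <- data.frame(threshold = thr, fpr = pts[, "fpr"], tpr = pts[, "tpr"])
  out <- out[order(out$fpr, out$tpr), ]
  rownames(out) <- NULL
  class(out) <- c("roc_curve", "data.frame")
  out
}

#' Area under an ROC curve (trapezoidal rule)
#'
#' Equals the Mann-Whitney pairwise-comparison statistic: the probability a
#' random positive item outscores a random negative one, ties counted 1/2.
#'
#' @param curve a `roc_curve`.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(curve) {
  fpr <- curve$fpr; tpr <- curve$tpr
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}
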