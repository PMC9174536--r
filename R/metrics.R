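# Pixel-level evaluation: confusion counts, sensitivity / specificity /
# accuracy, and ROC/AUC over pooled test-set pixels.

#' Pixel confusion counts
#'
#' Thresholds the prediction (`p >= threshold` is vessel) and counts
#' true/false positives/negatives against the binary mask.
#'
#' @param y Binary mask (or list of masks).
#' @param p Prediction raster in \[0, 1\] (or list, matching `y`).
#' @param threshold Decision threshold in (0, 1), default 0.5.
#' @return A list of class `confusion_counts` with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(y, p, threshold = 0.5) {
  if (!is.list(y)) { y <- list(y); p <- list(p) }
  yy <- unlist(lapply(y, as.vector), use.names = FALSE)
  pp <- unlist(lapply(p, as.vector), use.names = FALSE)
  check_same_shape(yy, pp)
  pos <- pp >= threshold
  out <- list(TP = sum(pos & yy == 1), TN = sum(!pos & yy == 0),
              FP = sum(pos & yy == 0), FN = sum(!pos & yy == 1))
  structure(out, class = "confusion_counts")
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' `SE = TP / (TP + FN)`, `SP = TN / (TN + FP)`,
#' `ACC = (TP + TN) / (TP + TN + FP + FN)`.  A zero denominator yields `NA`
#' for that metric and sets the `undefined` attribute rather than erroring.
#'
#' @param counts A `confusion_counts` object (or list with TP/TN/FP/FN).
#' @return Named numeric vector `c(sensitivity, specificity, accuracy)`,
#'   with attribute `undefined` naming any metric with an empty class.
#' @export
se_sp_acc <- function(counts) {
  undef <- character(0)
  se <- if (counts$TP + counts$FN > 0) counts$TP / (counts$TP + counts$FN) else {
    undef <- c(undef, "sensitivity"); NA_real_
  }
  sp <- if (counts$TN + counts$FP > 0) counts$TN / (counts$TN + counts$FP) else {
    undef <- c(undef, "specificity"); NA_real_
  }
  tot <- counts$TP + counts$TN + counts$FP + counts$FN
  acc <- if (tot > 0) (counts$TP + counts$TN) / tot else {
    undef <- c(undef, "accuracy"); NA_real_
  }
  structure(c(sensitivity = se, specificity = sp, accuracy = acc),
            undefined = undef)
}

#' ROC curve and AUC over pooled pixels
#'
#' Builds the ROC curve over all unique score thresholds of the pooled
#' pixels and integrates it by the trapezoidal rule.  This equals the rank
#' statistic `P(score_vessel > score_background) + 0.5 * P(tie)`.
#'
#' @param y Binary mask or list of masks.
#' @param p Prediction raster(s) matching `y`.
#' @return List with `roc` (data frame of `threshold`, `fpr`, `tpr`,
#'   running from (0,0) to (1,1)) and `auc`; `auc` is `NA` with the
#'   `undefined` attribute set when only one class is present.
#' @export
roc_auc <- function(y, p) {
  if (!is.list(y)) { y <- list(y); p <- list(p) }
  yy <- unlist(lapply(y, as.vector), use.names = FALSE)
  pp <- unlist(lapply(p, as.vector), use.names = FALSE)
  check_same_shape(yy, pp)
  npos <- sum(yy == 1); nneg <- sum(yy == 0)
  if (npos == 0L || nneg == 0L) {
    return(structure(list(roc = NULL, auc = NA_real_), undefined = "auc"))
  }
  ord <- order(pp, decreasing = TRUE)
  ys <- yy[ord]; ps <- pp[ord]
  tp <- cumsum(ys == 1); fp <- cumsum(ys == 0)
  last <- c(ps[-1] != ps[-length(ps)], TRUE)  # keep one point per unique score
  tpr <- c(0, tp[last] / npos)
  fpr <- c(0, fp[last] / nneg)
  thr <- c(Inf, ps[last])
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}

# Rank-statistic AUC (midrank form); independent of the trapezoid route.
auc_rank <- function(y, p) {
  yy <- as.vector(if (is.list(y)) unlist(y) else y)
  pp <- as.vector(if (is.list(p)) unlist(p) else p)
  npos <- sum(yy == 1); nneg <- sum(yy == 0)
  r <- rank(pp)
  (sum(r[yy == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Full metrics report for a prediction set
#'
#' Confusion counts at the given threshold, sensitivity / specificity /
#' accuracy, and pooled ROC/AUC.
#'
#' @inheritParams confusion_counts
#' @return List of class `metrics_report`: `counts`, `sensitivity`,
#'   `specificity`, `accuracy`, `auc`, `roc`, `threshold`, `undefined`.
#' @export
metrics_report <- function(y, p, threshold = 0.5) {
  counts <- confusion_counts(y, p, threshold)
  ssa <- se_sp_acc(counts)
  ra <- roc_auc(y, p)
  structure(list(counts = counts,
                 sensitivity = unname(ssa["sensitivity"]),
                 specificity = unname(ssa["specificity"]),
                 accuracy = unname(ssa["accuracy"]),
                 auc = ra$auc, roc = ra$roc, threshold = threshold,
                 undefined = c(attr(ssa, "undefined"), attr(ra, "undefined"))),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("pixels: TP %d  TN %d  FP %d  FN %d\n",
              x$counts$TP, x$counts$TN, x$counts$FP, x$counts$FN))
  cat(sprintf("SE %.4f  SP %.4f  ACC %.4f  AUC %.4f  (threshold %.2f)\n",
              x$sensitivity, x$specificity, x$accuracy, x$auc, x$threshold))
  if (length(x$undefined)) cat("undefined:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}
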