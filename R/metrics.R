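# Confusion-matrix metrics, ROC / PR curves and their areas.
# All computations are deliberately transparent so they can be verified
# against brute-force oracles (pairwise concordance, exhaustive threshold
# enumeration) in the test suite.

#' Confusion counts at a threshold
#'
#' @param labels Integer/numeric vector of true labels in `{0, 1}`.
#' @param scores Numeric vector of predicted scores; a sample is called
#'   positive when `score >= threshold`.
#' @param threshold Decision threshold, default 0.5.
#' @return Named list with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(labels, scores, threshold = 0.5) {
  check_labels_scores(labels, scores)
  pred <- as.integer(scores >= threshold)
  list(TP = sum(pred == 1L & labels == 1L),
       FP = sum(pred == 1L & labels == 0L),
       TN = sum(pred == 0L & labels == 0L),
       FN = sum(pred == 0L & labels == 1L))
}

check_labels_scores <- function(labels, scores) {
  if (length(labels) == 0L || length(labels) != length(scores)) {
    stop("labels and scores must be non-empty and of equal length")
  }
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  invisible(TRUE)
}

#' F1 score from recall and precision
#'
#' Harmonic mean `2 * recall * precision / (recall + precision)`; defined
#' as 0 (with a warning) when both are zero.
#'
#' @param recall,precision Values in `[0, 1]`.
#' @return The F1 score.
#' @export
#' @examples
#' f1_score(0.625, 1.0)  # 0.769...
f1_score <- function(recall, precision) {
  stopifnot(recall >= 0, recall <= 1, precision >= 0, precision <= 1)
  if (recall + precision == 0) {
    warning("recall and precision both zero; F1 defined as 0")
    return(0)
  }
  2 * recall * precision / (recall + precision)
}

#' ROC curve and AUROC
#'
#' Thresholds are taken at each unique score (ties grouped at one
#' threshold).  The curve starts at (0, 0) and ends at (1, 1); the area
#' is computed by the trapezoidal rule, which equals the Mann-Whitney
#' concordance probability (ties counted 1/2).
#'
#' @param labels Vector in `{0, 1}`; both classes must be present.
#' @param scores Numeric scores, larger = more positive.
#' @return List with `points` (data.frame `fpr`, `tpr`) and `auroc`.
#' @export
roc_curve <- function(labels, scores) {
  check_labels_scores(labels, scores)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L) {
    stop("roc_curve requires both classes present")
  }
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  # group tied scores: cumulative counts evaluated at the end of each group
  grp_end <- which(diff(sc) != 0)
  grp_end <- c(grp_end, length(sc))
  tp <- cumsum(lab == 1)[grp_end]
  fp <- cumsum(lab == 0)[grp_end]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auroc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auroc = auroc)
}

#' Precision-recall curve and AUPR
#'
#' Precision and recall are evaluated at each unique-score threshold
#' (ties grouped).  The default area is average precision -- the
#' step-wise sum `sum((R_k - R_(k-1)) * P_k)` -- which avoids the
#' optimistic linear interpolation of trapezoids in PR space; the
#' trapezoidal alternative is available via `method`.
#'
#' @param labels Vector in `{0, 1}`; at least one positive required.
#' @param scores Numeric scores.
#' @param method `"average_precision"` (default) or `"trapezoid"`.
#' @return List with `points` (data.frame `recall`, `precision`) and
#'   `aupr`.
#' @export
pr_curve <- function(labels, scores,
                     method = c("average_precision", "trapezoid")) {
  method <- match.arg(method)
  check_labels_scores(labels, scores)
  n_pos <- sum(labels == 1)
  if (n_pos == 0L) stop("pr_curve requires at least one positive")
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  grp_end <- c(which(diff(sc) != 0), length(sc))
  tp <- cumsum(lab == 1)[grp_end]
  n_called <- grp_end
  recall <- tp / n_pos
  precision <- tp / n_called
  aupr <- if (method == "average_precision") {
    sum(diff(c(0, recall)) * precision)
  } else {
    r <- c(0, recall)
    p <- c(precision[1], precision)  # extend left with first precision
    sum(diff(r) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
  }
  list(points = data.frame(recall = recall, precision = precision),
       aupr = aupr)
}

#' Full evaluation report
#'
#' Computes accuracy, recall, precision, F1, AUROC and AUPR for a set of
#' scored samples, in the conventional benchmark column order.
#'
#' @param labels Vector in `{0, 1}`.
#' @param scores Numeric scores in `[0, 1]`.
#' @param threshold Decision threshold for the thresholded metrics.
#' @return A one-row `data.frame` with columns `accuracy`, `auroc`,
#'   `aupr`, `recall`, `precision`, `f1`.
#' @export
metrics_report <- function(labels, scores, threshold = 0.5) {
  cm <- confusion(labels, scores, threshold)
  n <- cm$TP + cm$FP + cm$TN + cm$FN
  recall <- if (cm$TP + cm$FN > 0) cm$TP / (cm$TP + cm$FN) else NA_real_
  precision <- if (cm$TP + cm$FP > 0) cm$TP / (cm$TP + cm$FP) else NA_real_
  f1 <- if (!is.na(recall) && !is.na(precision) && recall + precision > 0) {
    f1_score(recall, precision)
  } else NA_real_
  data.frame(
    accuracy = (cm$TP + cm$TN) / n,
    auroc = roc_curve(labels, scores)$auroc,
    aupr = pr_curve(labels, scores)$aupr,
    recall = recall,
    precision = precision,
    f1 = f1
  )
}
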