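#' ROC curve of a score as a binary classifier
#'
#' Higher score is taken as evidence for the positive class (no automatic
#' direction flip — a signature that scores positives lower has genuinely
#' failed and should be seen to fail). One curve point per distinct score
#' value plus the two endpoints; tied scores collapse to a single threshold,
#' which makes the trapezoidal AUC exactly the tie-aware Mann-Whitney
#' statistic U/(n1*n0).
#'
#' @param scores numeric vector.
#' @param labels logical/0-1 vector, `TRUE`/1 = positive class; both classes
#'   must be present.
#' @return object of class `roc_result`: list with `thresholds` (descending,
#'   starting at `Inf`), `fpr`, `tpr` (non-decreasing from 0 to 1), `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (anyNA(scores) || anyNA(labels)) stop("scores/labels must be non-missing")
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) stop("labels must contain both classes")

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  last_of_tie <- c(s[-1L] != s[-length(s)], TRUE)
  tp <- cumsum(l)[last_of_tie]
  fp <- cumsum(!l)[last_of_tie]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  thresholds <- c(Inf, s[last_of_tie])
  auc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
  structure(list(thresholds = thresholds, fpr = fpr, tpr = tpr, auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> %d curve points, AUC = %.4f\n", length(x$tpr), x$auc))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Scalar shortcut for [roc_curve()]`$auc`: the probability that a random
#' positive scores above a random negative, ties counted one half.
#'
#' @inheritParams roc_curve
#' @return AUC in \[0,1\].
#' @export
auc <- function(scores, labels) roc_curve(scores, labels)$auc

#' ROC curve points as a data.frame
#'
#' @param r a `roc_result`.
#' @return data.frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(r) {
  data.frame(threshold = r$thresholds, fpr = r$fpr, tpr = r$tpr)
}
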