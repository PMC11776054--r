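#' Confusion matrix
#'
#' K x K count matrix with rows = true class, columns = predicted class
#' (the orientation used throughout the package's reports and plots).
#'
#' @param truth,estimate Character/factor vectors of equal length.
#' @param classes Ordered class set; defaults to the sorted union of labels
#'   seen in `truth` and `estimate`.
#' @return A `confusion_matrix` (integer matrix with class attributes).
#' @examples
#' cm <- confusion_matrix(c("A", "A", "B"), c("A", "B", "B"))
#' balanced_accuracy(cm); mcc(cm)
#' @export
confusion_matrix <- function(truth, estimate, classes = NULL) {
  truth <- as.character(truth)
  estimate <- as.character(estimate)
  if (length(truth) != length(estimate)) {
    abort("`truth` and `estimate` must have equal length.")
  }
  if (length(truth) == 0) {
    abort("Cannot build a confusion matrix from zero samples.",
          class = "ligandpath_undefined_metric")
  }
  classes <- classes %||% sort(union(truth, estimate))
  bad <- setdiff(union(truth, estimate), classes)
  if (length(bad) > 0) {
    abort(paste0("Label(s) outside the declared class set: ",
                 paste(bad, collapse = ", ")))
  }
  m <- table(factor(truth, levels = classes), factor(estimate, levels = classes))
  m <- matrix(as.integer(m), nrow = length(classes),
              dimnames = list(truth = classes, predicted = classes))
  structure(m, class = c("confusion_matrix", "matrix", "array"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> rows = truth, columns = predicted\n")
  print(unclass(x))
  invisible(x)
}

#' Balanced accuracy
#'
#' Mean per-class recall: `BA = (1/K') * sum_k TP_k / (TP_k + FN_k)`,
#' averaged over the K' classes that actually occur in the truth (classes
#' absent from the truth are excluded so test sets lacking some tunnels
#' remain scoreable).  A constant dominant-class predictor scores 1/K' --
#' 0.50 with two classes present, 1/9 ~= 0.11 with nine.
#'
#' @param cm A [confusion_matrix()].
#' @return Balanced accuracy in \[0, 1\].
#' @export
balanced_accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  t_k <- rowSums(cm)
  present <- t_k > 0
  if (!any(present)) {
    abort("No samples in the confusion matrix.",
          class = "ligandpath_undefined_metric")
  }
  mean(diag(cm)[present] / t_k[present])
}

#' Multiclass Matthews correlation coefficient
#'
#' `MCC = (c*s - sum_k t_k p_k) / sqrt((s^2 - sum_k p_k^2) (s^2 - sum_k t_k^2))`
#' where `s` is the number of samples, `c` the number predicted correctly,
#' `t_k` / `p_k` the true / predicted occurrences of class k.  When the
#' denominator is zero (constant predictor or constant truth) the value is
#' defined as 0.
#'
#' @param cm A [confusion_matrix()].
#' @return MCC in \[-1, 1\].
#' @export
mcc <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  s <- sum(cm)
  if (s == 0) {
    abort("No samples in the confusion matrix.",
          class = "ligandpath_undefined_metric")
  }
  c_ <- sum(diag(cm))
  t_k <- rowSums(cm)
  p_k <- colSums(cm)
  num <- c_ * s - sum(t_k * p_k)
  den <- sqrt((s^2 - sum(p_k^2)) * (s^2 - sum(t_k^2)))
  if (den == 0) return(0)
  num / den
}

#' ROC curve and AUC
#'
#' Receiver operating characteristic for a binary task: true positive rate
#' `TPR = TP / (TP + FN)` against false positive rate `FPR = FP / (FP + TN)`
#' at every distinct score threshold.  AUC is computed by the trapezoidal
#' rule and equals the Mann-Whitney concordant-pair statistic (ties counted
#' half).
#'
#' @param truth Binary labels.
#' @param score Numeric scores; higher means more likely positive.
#' @param positive The positive class; default `"primary"`.
#' @return A `roc_result`: `points` tibble (`threshold`, `fpr`, `tpr`,
#'   from (0,0) to (1,1)) and `auc`.
#' @examples
#' r <- roc_curve(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.3), positive = 1)
#' r$auc  # 0.75
#' @export
roc_curve <- function(truth, score, positive = "primary") {
  truth <- as.character(truth)
  if (length(truth) != length(score)) {
    abort("`truth` and `score` must have equal length.")
  }
  pos <- truth == as.character(positive)
  if (!any(pos) || all(pos)) {
    abort("ROC needs both classes present in the truth.",
          class = "ligandpath_undefined_roc")
  }
  ord <- order(score, decreasing = TRUE)
  pos <- pos[ord]
  score <- score[ord]
  # cumulative counts at each distinct threshold (score >= threshold)
  keep <- c(diff(score) != 0, TRUE)
  tp <- cumsum(pos)[keep]
  fp <- cumsum(!pos)[keep]
  P <- sum(pos); N <- sum(!pos)
  points <- tibble(
    threshold = c(Inf, score[keep]),
    fpr = c(0, fp / N),
    tpr = c(0, tp / P)
  )
  auc <- sum(diff(points$fpr) * (head(points$tpr, -1) + points$tpr[-1]) / 2)
  structure(list(points = points, auc = auc, positive = as.character(positive)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> ", nrow(x$points), " points, AUC = ",
      sprintf("%.3f", x$auc), " (positive class: ", x$positive, ")\n", sep = "")
  invisible(x)
}

#' Collapse pathway labels to the binary scheme
#'
#' T1, T2 and T7 (the high-probability tunnels sharing the initial unbinding
#' segment) map to `"primary"`; T3--T6, T8, T9 and T10 to `"secondary"`.
#' Used both to build binary training labels and to score the multiclass
#' model on the binary task.
#'
#' @param labels Vector of pathway ids in `T1..T10`.
#' @return Character vector of `"primary"` / `"secondary"`, same length and
#'   order.
#' @examples
#' collapse_to_binary(c("T7", "T10", "T3"))
#' @export
collapse_to_binary <- function(labels) {
  labels <- as.character(labels)
  valid <- paste0("T", 1:10)
  bad <- setdiff(unique(labels), valid)
  if (length(bad) > 0) {
    abort(paste0("Unknown pathway label(s): ", paste(bad, collapse = ", "),
                 " (expected T1..T10)."),
          class = "ligandpath_invalid_label")
  }
  ifelse(labels %in% c("T1", "T2", "T7"), "primary", "secondary")
}
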