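#' Confusion matrix
#'
#' @param true_labels,predicted_labels integer vectors of 0-based classes.
#' @param Nc number of classes.
#' @return An \code{Nc x Nc} integer matrix of class \code{"confusion_matrix"};
#'   rows are true classes, columns predicted classes.
#' @export
#' @examples
#' confusion_matrix(c(0, 1), c(0, 1), 2)
confusion_matrix <- function(true_labels, predicted_labels, Nc) {
  stopifnot(length(true_labels) == length(predicted_labels))
  true_labels <- as.integer(true_labels)
  predicted_labels <- as.integer(predicted_labels)
  if (any(c(true_labels, predicted_labels) < 0L) ||
      any(c(true_labels, predicted_labels) >= Nc))
    stop_config("labels must lie in [0, %d)", Nc)
  cm <- matrix(0L, Nc, Nc,
               dimnames = list(true = 0:(Nc - 1L), pred = 0:(Nc - 1L)))
  for (i in seq_along(true_labels))
    cm[true_labels[i] + 1L, predicted_labels[i] + 1L] <-
      cm[true_labels[i] + 1L, predicted_labels[i] + 1L] + 1L
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Classification accuracy from a confusion matrix
#'
#' Trace over total: the multiclass generalization of
#' (TP+TN)/(TP+TN+FP+FN).
#'
#' @param cm a confusion matrix (any square count matrix).
#' @return Fraction of correctly classified trials.
#' @export
accuracy <- function(cm) {
  total <- sum(cm)
  if (total <= 0) stop_config("empty confusion matrix")
  sum(diag(as.matrix(cm))) / total
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement \eqn{(p_a - p_e) / (1 - p_e)} with
#' \eqn{p_a} the observed accuracy (trace/total) and \eqn{p_e} the expected
#' agreement from the row/column marginals.
#'
#' @param cm a square count matrix.
#' @return Kappa in \code{[-1, 1]}.
#' @export
#' @examples
#' cohen_kappa(matrix(c(40, 20, 10, 30), 2)) # 0.4
cohen_kappa <- function(cm) {
  cm <- as.matrix(cm)
  total <- sum(cm)
  if (total <= 0) stop_config("empty confusion matrix")
  pa <- sum(diag(cm)) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (abs(1 - pe) < 1e-12)
    stop_config("kappa undefined: expected agreement p_e = 1")
  (pa - pe) / (1 - pe)
}

#' Paired Wilcoxon signed-rank comparison of per-subject accuracies
#'
#' Two-sided signed-rank test (stats::wilcox.test, paired); zero differences
#' are dropped per that implementation's policy, which is recorded in the
#' result. If every difference is zero the test is degenerate and p = 1 is
#' returned with a warning.
#'
#' @param accuracies_a,accuracies_b equal-length (>= 5) per-subject accuracy
#'   vectors.
#' @return List with \code{p_value}, \code{statistic}, \code{policy}.
#' @export
wilcoxon_compare <- function(accuracies_a, accuracies_b) {
  stopifnot(length(accuracies_a) == length(accuracies_b))
  if (length(accuracies_a) < 5L)
    stop_config("need >= 5 paired subjects for the signed-rank test")
  d <- accuracies_a - accuracies_b
  if (all(d == 0)) {
    warning("degenerate comparison: all paired differences are zero; p = 1")
    return(list(p_value = 1, statistic = NA_real_,
                policy = "all differences zero; test skipped"))
  }
  wt <- suppressWarnings(stats::wilcox.test(accuracies_a, accuracies_b,
                                            paired = TRUE))
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       policy = "zero differences dropped; ties mid-ranked (stats::wilcox.test)")
}
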