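#' Confusion matrix
#'
#' `counts[i, j]` is the number of samples of true class `i` predicted as
#' class `j`.
#'
#' @param y_true,y_pred integer labels in 1..n_classes, equal length.
#' @param n_classes number of classes (default: max label seen).
#' @param class_names optional class names for dimnames.
#' @return n x n integer matrix of class `confusion_matrix`.
#' @examples
#' confusion(c(1, 1, 2), c(1, 2, 2), 2)
#' @export
confusion <- function(y_true, y_pred, n_classes = max(y_true, y_pred),
                      class_names = NULL) {
  if (length(y_true) != length(y_pred)) stop("label vectors differ in length")
  if (any(y_true < 1 | y_true > n_classes) || any(y_pred < 1 | y_pred > n_classes)) {
    stop("labels out of 1..n_classes range")
  }
  cm <- matrix(0L, n_classes, n_classes)
  tab <- table(factor(y_true, levels = seq_len(n_classes)),
               factor(y_pred, levels = seq_len(n_classes)))
  cm[] <- as.integer(tab)
  if (!is.null(class_names)) dimnames(cm) <- list(true = class_names,
                                                  predicted = class_names)
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' Classification accuracy metrics
#'
#' * `overall_accuracy`: trace / total — the fraction of correctly
#'   classified samples.
#' * `average_accuracy`: macro average of per-class recall
#'   (`x_ii / sum_j x_ij`).
#' * `kappa`: Cohen's chance-corrected agreement
#'   `(p_o - p_e) / (1 - p_e)` with `p_o` the overall accuracy and
#'   `p_e = sum_i row_i * col_i / total^2`.
#'
#' @param cm a [confusion()] matrix.
#' @return a proportion (or coefficient in [-1, 1] for kappa). `kappa`
#'   returns `NA` with a warning for the degenerate single-cell matrix where
#'   `p_e == 1`.
#' @examples
#' cm <- matrix(c(45, 10, 5, 40), 2) # OA 0.85, kappa 0.70
#' overall_accuracy(cm)
#' kappa(cm)
#' @name accuracy_metrics
NULL

#' @rdname accuracy_metrics
#' @export
overall_accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  sum(diag(cm)) / total
}

#' @rdname accuracy_metrics
#' @export
average_accuracy <- function(cm) {
  rs <- rowSums(cm)
  if (any(rs == 0)) {
    stop(sprintf("class %s has no true samples; per-class recall undefined",
                 paste(which(rs == 0), collapse = ", ")))
  }
  mean(diag(cm) / rs)
}

#' @rdname accuracy_metrics
#' @export
kappa <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  p_o <- sum(diag(cm)) / total
  p_e <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (abs(1 - p_e) < .Machine$double.eps * 8) {
    warning("degenerate confusion matrix: p_e == 1, kappa undefined")
    return(NA_real_)
  }
  (p_o - p_e) / (1 - p_e)
}

metric_row <- function(y_true, y_pred, n_classes) {
  cm <- confusion(y_true, y_pred, n_classes)
  c(AA = average_accuracy(cm), OA = overall_accuracy(cm),
    Kappa100 = 100 * kappa(cm))
}
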