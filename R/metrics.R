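#' Confusion matrix of true vs predicted labels
#'
#' @param truth,estimate `label_set` objects on the same samples
#'   (aligned by `sample_id`).
#' @return A K x K integer matrix of class `conf_mat` with true classes
#'   in rows and predicted classes in columns.
#' @export
confusion_matrix <- function(truth, estimate) {
  stopifnot(inherits(truth, "label_set"), inherits(estimate, "label_set"))
  sets <- align_sets(list(truth, estimate))
  cls <- ls_class_names(sets[[1]])
  K <- length(cls)
  cm <- table(factor(sets[[1]]$label, levels = 0:(K - 1)),
              factor(sets[[2]]$label, levels = 0:(K - 1)))
  cm <- matrix(as.integer(cm), K, K, dimnames = list(truth = cls, predicted = cls))
  class(cm) <- c("conf_mat", class(cm))
  cm
}

#' Balanced accuracy: the unweighted mean of per-class recall
#'
#' Under class imbalance, plain accuracy rewards predicting the majority
#' class; balanced accuracy weights every class equally, so a classifier
#' that always emits one fixed class scores exactly `1/K`.
#'
#' @param cm A `conf_mat` (or plain K x K count matrix, rows = truth).
#' @return A scalar in `[0, 1]`.
#' @export
balanced_accuracy <- function(cm) {
  cm <- unclass(cm)
  support <- rowSums(cm)
  if (any(support == 0)) {
    abort("Balanced accuracy is undefined: a true class has no samples.")
  }
  mean(diag(cm) / support)
}

#' Support-weighted one-vs-rest detection metrics
#'
#' Computes precision, recall (sensitivity), specificity, and F1 for
#' each class in a one-vs-rest reduction, then averages them with
#' weights proportional to true-class support (so weighted recall always
#' equals plain accuracy). Cells with a zero denominator (e.g. a class
#' never predicted makes precision undefined) score 0 and are flagged in
#' the per-class table with a warning.
#'
#' @param cm A `conf_mat`.
#' @return An object of class `ovr_metrics`; [tidy()] gives the
#'   per-class table, [glance()] the support-weighted averages.
#' @export
weighted_ovr_metrics <- function(cm) {
  cmm <- unclass(cm)
  K <- nrow(cmm)
  n <- sum(cmm)
  support <- rowSums(cmm)
  if (any(support == 0)) {
    abort("Metrics undefined: a true class has no samples.")
  }
  tp <- diag(cmm)
  fp <- colSums(cmm) - tp
  fn <- rowSums(cmm) - tp
  tn <- n - tp - fp - fn

  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  specificity <- safe_div(tn, tn + fp)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  zero_division <- (tp + fp) == 0 | (precision + recall) == 0
  if (any(zero_division)) {
    warn(sprintf(
      "Zero-division in %d per-class cell(s); scored 0 by convention.",
      sum(zero_division)))
  }

  per_class <- tibble::tibble(
    class = rownames(cmm) %||% as.character(seq_len(K)),
    support = as.integer(support),
    precision = precision, recall = recall,
    specificity = specificity, f1 = f1,
    zero_division = zero_division
  )
  wt <- support / n
  weighted <- tibble::tibble(
    precision = sum(wt * precision), recall = sum(wt * recall),
    specificity = sum(wt * specificity), f1 = sum(wt * f1)
  )
  structure(list(per_class = per_class, weighted = weighted, n = n),
            class = "ovr_metrics")
}

#' @export
print.ovr_metrics <- function(x, ...) {
  cat("One-vs-rest metrics (support-weighted averages):\n")
  print(x$weighted, ...)
  invisible(x)
}

#' @rdname weighted_ovr_metrics
#' @param x An `ovr_metrics` object.
#' @param ... Unused.
#' @export
tidy.ovr_metrics <- function(x, ...) x$per_class

#' @rdname weighted_ovr_metrics
#' @export
glance.ovr_metrics <- function(x, ...) x$weighted
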