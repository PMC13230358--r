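# Mann-Whitney AUC of `scores` for separating positives from negatives;
# ties count 1/2. NA when either group is empty.
auc_binary <- function(scores, positive) {
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' One-vs-one ROC AUC for multi-class probabilities
#'
#' For every unordered class pair (a, b), samples are restricted to the
#' two classes and both directed AUCs are computed — class a's
#' probability column scoring a against b, and class b's column scoring
#' b against a — then averaged. The final value is the mean over all
#' `K(K-1)/2` pairs, so each pair counts equally regardless of its
#' prevalence. Pairs in which one class has no samples are skipped with
#' a warning and excluded from the average.
#'
#' @param pred A `pred_set`.
#' @param truth A `label_set` aligned by `sample_id`.
#' @return A scalar in `[0, 1]`.
#' @export
roc_auc_ovo <- function(pred, truth) {
  stopifnot(inherits(pred, "pred_set"), inherits(truth, "label_set"))
  sets <- align_sets(list(pred, truth))
  probs <- ps_probs(sets[[1]])
  y <- sets[[2]]$label
  K <- ncol(probs)
  if (K < 2) abort("Need at least two classes.")
  pair_aucs <- c()
  skipped <- 0L
  for (a in 0:(K - 2)) {
    for (b in (a + 1):(K - 1)) {
      in_pair <- y == a | y == b
      if (sum(y == a) == 0 || sum(y == b) == 0) {
        skipped <- skipped + 1L
        next
      }
      auc_ab <- auc_binary(probs[in_pair, a + 1], y[in_pair] == a)
      auc_ba <- auc_binary(probs[in_pair, b + 1], y[in_pair] == b)
      pair_aucs <- c(pair_aucs, (auc_ab + auc_ba) / 2)
    }
  }
  if (skipped > 0) {
    warn(sprintf("Skipped %d class pair(s) with an empty class.", skipped))
  }
  if (length(pair_aucs) == 0) abort("No class pair had both classes present.")
  mean(pair_aucs)
}

#' Empirical ROC curve of a binary score
#'
#' Threshold-sweep ROC: one point per distinct score value, anchored at
#' (0, 0) and (1, 1).
#'
#' @param scores Numeric scores (higher = more positive).
#' @param positive Logical vector marking positive samples.
#' @return A tibble with columns `fpr`, `tpr`.
#' @export
roc_points <- function(scores, positive) {
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) abort("Both classes must be present.")
  ord <- order(scores, decreasing = TRUE)
  pos <- positive[ord]
  s <- scores[ord]
  tp <- cumsum(pos)
  fp <- cumsum(!pos)
  keep <- c(s[-1] != s[-length(s)], TRUE) # last index of each distinct score
  tibble::tibble(fpr = c(0, fp[keep] / n_neg), tpr = c(0, tp[keep] / n_pos))
}

#' Aggregate many ROC curves onto a common grid
#'
#' Each curve is linearly interpolated onto a fixed grid of
#' false-positive rates spanning `[0, 1]` (101 points by default, with
#' (0,0) and (1,1) anchors added if absent); the pointwise mean and
#' percentile 2.5/97.5 band across curves are returned. Degenerate
#' single-point curves reduce to the anchors. This is the machinery
#' behind "mean ROC with 95% CI" figures built from bootstrapped,
#' binarized one-vs-one comparisons.
#'
#' @param curves A list of tibbles/data frames with columns `fpr`, `tpr`.
#' @param grid_size Number of FPR grid points.
#' @return An object of class `aggregated_roc`; [tidy()] returns the
#'   grid tibble (`fpr`, `mean_tpr`, `ci_low`, `ci_high`),
#'   [autoplot()] draws the band.
#' @export
aggregate_roc <- function(curves, grid_size = 101) {
  if (length(curves) < 1) abort("Need at least one curve.")
  grid <- seq(0, 1, length.out = grid_size)
  interp <- purrr::map(curves, function(cv) {
    fpr <- c(0, cv$fpr, 1)
    tpr <- c(0, cv$tpr, 1)
    ord <- order(fpr, tpr)
    approx(fpr[ord], tpr[ord], xout = grid, ties = max)$y
  })
  mat <- do.call(rbind, interp) # n_curves x grid_size
  structure(
    list(
      grid = tibble::tibble(
        fpr = grid,
        mean_tpr = colMeans(mat),
        ci_low = apply(mat, 2, quantile, probs = 0.025),
        ci_high = apply(mat, 2, quantile, probs = 0.975)
      ),
      n_curves = length(curves)
    ),
    class = "aggregated_roc"
  )
}

#' @rdname aggregate_roc
#' @param x An `aggregated_roc` object.
#' @param ... Unused.
#' @export
tidy.aggregated_roc <- function(x, ...) x$grid

#' @rdname aggregate_roc
#' @export
glance.aggregated_roc <- function(x, ...) {
  # trapezoid area under the aggregated mean curve
  g <- x$grid
  auc <- sum(diff(g$fpr) * (head(g$mean_tpr, -1) + g$mean_tpr[-1]) / 2)
  tibble::tibble(n_curves = x$n_curves, mean_auc = auc)
}

#' @rdname aggregate_roc
#' @param object An `aggregated_roc` object.
#' @export
autoplot.aggregated_roc <- function(object, ...) {
  g <- object$grid
  ggplot2::ggplot(g, ggplot2::aes(x = .data$fpr, y = .data$mean_tpr)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = "False-positive rate", y = "True-positive rate",
      title = sprintf("Aggregated ROC (%d curves, 95%% band)",
                      object$n_curves)
    ) +
    ggplot2::coord_equal()
}
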