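#' Reliability diagram and binned expected calibration error
#'
#' Bins each sample by its confidence — the maximum class probability —
#' and compares, per bin, the mean confidence against the fraction of
#' correct top-class decisions. The expected calibration error (ECE) is
#' the count-weighted mean absolute confidence/accuracy gap:
#' `ECE = sum_b (n_b / n) * |acc_b - conf_b|`. A well-calibrated
#' classifier has bars on the diagonal and ECE near 0.
#'
#' Two binning schemes are supported: `"fixed"` uses `n_bins`
#' equal-width bins on `[0, 1]`, each interval left-closed/right-open
#' with the last bin closed; `"quantile"` places edges at confidence
#' quantiles so bins hold roughly equal counts (duplicate edges are
#' collapsed). Empty bins carry zero weight.
#'
#' Majority-vote ensembles are hard-label objects without probabilities,
#' so calibration is undefined for them; passing a `label_set` is an
#' error.
#'
#' @param pred A `pred_set` of softmax probabilities.
#' @param truth A `label_set` aligned by `sample_id`.
#' @param n_bins Number of bins (default 15, the usual fixed-bin
#'   convention for ECE).
#' @param scheme `"fixed"` or `"quantile"`.
#' @return An object of class `reliability_diagram` with elements
#'   `bins` (tibble: `bin`, `lower`, `upper`, `count`, `conf`, `acc`),
#'   `ece`, `n`, `n_bins`, `scheme`, `edges`. [tidy()] returns the bin
#'   table, [glance()] the scalars, [autoplot()] the diagram.
#' @examples
#' ps <- prediction_set(data.frame(sample_id = c("a", "b"),
#'                                 A = c(0.9, 0.2), B = c(0.1, 0.8)))
#' y <- label_set(c("a", "b"), c(0, 1), c("A", "B"))
#' reliability(ps, y, n_bins = 10)
#' @export
reliability <- function(pred, truth, n_bins = 15, scheme = c("fixed", "quantile")) {
  if (inherits(pred, "label_set")) {
    abort(paste0(
      "Calibration is undefined for hard-label (e.g. majority-vote) ",
      "ensembles: no class probabilities are available."))
  }
  stopifnot(inherits(pred, "pred_set"), inherits(truth, "label_set"))
  scheme <- match.arg(scheme)
  if (length(n_bins) != 1 || is.na(n_bins) || n_bins < 1) {
    abort("`n_bins` must be a positive integer.")
  }
  n_bins <- as.integer(n_bins)
  sets <- align_sets(list(pred, truth))
  probs <- ps_probs(sets[[1]])
  y <- sets[[2]]$label
  conf <- apply(probs, 1, max)
  correct <- (max.col(probs, ties.method = "first") - 1L) == y
  n <- length(conf)

  if (scheme == "fixed") {
    edges <- seq(0, 1, length.out = n_bins + 1)
  } else {
    edges <- unname(quantile(conf, probs = seq(0, 1, length.out = n_bins + 1)))
    edges[1] <- 0
    edges[length(edges)] <- 1
    edges <- unique(edges)
    if (length(edges) < n_bins + 1) {
      inform(sprintf("Collapsed duplicate quantile edges: %d bin(s) used.",
                     length(edges) - 1L))
    }
  }
  B <- length(edges) - 1L
  bin <- findInterval(conf, edges, rightmost.closed = TRUE)
  bin[bin < 1L] <- 1L

  count <- tabulate(bin, nbins = B)
  bin_conf <- rep(NA_real_, B)
  bin_acc <- rep(NA_real_, B)
  for (b in which(count > 0)) {
    in_b <- bin == b
    bin_conf[b] <- mean(conf[in_b])
    bin_acc[b] <- mean(correct[in_b])
  }
  nonempty <- count > 0
  ece <- sum((count[nonempty] / n) * abs(bin_acc[nonempty] - bin_conf[nonempty]))

  structure(
    list(
      bins = tibble::tibble(
        bin = seq_len(B), lower = edges[-length(edges)], upper = edges[-1],
        count = count, conf = bin_conf, acc = bin_acc
      ),
      ece = ece, n = n, n_bins = B, scheme = scheme, edges = edges
    ),
    class = "reliability_diagram"
  )
}

#' Expected calibration error (scalar convenience wrapper)
#'
#' @inheritParams reliability
#' @return The ECE scalar in `[0, 1]`.
#' @export
ece <- function(pred, truth, n_bins = 15, scheme = c("fixed", "quantile")) {
  reliability(pred, truth, n_bins = n_bins, scheme = scheme)$ece
}

#' @export
print.reliability_diagram <- function(x, ...) {
  cat(sprintf("Reliability diagram: %d %s bins, n = %d, ECE = %.4f\n",
              x$n_bins, x$scheme, x$n, x$ece))
  print(x$bins, ...)
  invisible(x)
}

#' @rdname reliability
#' @param x A `reliability_diagram`.
#' @param ... Unused.
#' @export
tidy.reliability_diagram <- function(x, ...) x$bins

#' @rdname reliability
#' @export
glance.reliability_diagram <- function(x, ...) {
  tibble::tibble(ece = x$ece, n = x$n, n_bins = x$n_bins, scheme = x$scheme)
}

#' @rdname reliability
#' @param object A `reliability_diagram`.
#' @export
autoplot.reliability_diagram <- function(object, ...) {
  b <- dplyr::filter(object$bins, .data$count > 0)
  ggplot2::ggplot(b) +
    ggplot2::geom_rect(
      ggplot2::aes(xmin = .data$lower, xmax = .data$upper,
                   ymin = 0, ymax = .data$acc),
      fill = "steelblue", colour = "grey30", alpha = 0.8
    ) +
    ggplot2::geom_point(ggplot2::aes(x = .data$conf, y = .data$acc)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Confidence (top-class probability)", y = "Accuracy",
      title = sprintf("Reliability diagram (ECE = %.3f, n = %d)",
                      object$ece, object$n)
    )
}
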