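#' Seeded bootstrap resampling indices with class coverage
#'
#' Draws R with-replacement resamples of the test-set indices. Because
#' metrics such as balanced accuracy are undefined when a true class is
#' absent, replicates missing a class are redrawn (up to `max_attempts`
#' per replicate, then the run aborts); redraws are counted and
#' reported. Generating the index sets once and reusing them across
#' decision strategies makes strategy comparisons share resampling
#' noise, so two identical prediction sets yield identical bootstrap
#' summaries.
#'
#' @param truth A `label_set` (its labels drive the class-coverage
#'   check) or an integer `n` for unconstrained resampling.
#' @param R Number of replicates.
#' @param seed Integer seed; the draw sequence is fully reproducible.
#' @param require_all_classes Redraw replicates missing a class?
#' @param max_attempts Redraw budget per replicate.
#' @return A list of R integer index vectors of length n.
#' @export
bootstrap_indices <- function(truth, R = 100, seed = 1,
                              require_all_classes = TRUE,
                              max_attempts = 100) {
  if (R < 2) abort("Need R >= 2 replicates.")
  if (inherits(truth, "label_set")) {
    y <- truth$label
    n <- length(y)
    K <- length(ls_class_names(truth))
  } else {
    n <- as.integer(truth)
    y <- NULL
    require_all_classes <- FALSE
  }
  redraws <- 0L
  idx <- withr::with_seed(as.integer(seed), {
    purrr::map(seq_len(R), function(r) {
      for (attempt in seq_len(max_attempts)) {
        i <- sample.int(n, n, replace = TRUE)
        if (!require_all_classes ||
            length(unique(y[i])) == K) {
          return(i)
        }
        redraws <<- redraws + 1L
      }
      abort(sprintf(
        "Replicate %d missing a class after %d redraws; test set too small.",
        r, max_attempts))
    })
  })
  if (redraws > 0) {
    inform(sprintf("bootstrap_indices: %d replicate redraw(s) for class coverage.",
                   redraws))
  }
  idx
}

# Positional resample of a pred_set/label_set pair: duplicated draws get
# fresh unique ids so downstream id-aligned metrics stay valid.
resample_pair <- function(x, truth, idx) {
  new_ids <- paste0(truth$sample_id[idx], "#", seq_along(idx))
  y2 <- label_set(new_ids, truth$label[idx], ls_class_names(truth))
  if (is.null(x)) return(list(x = NULL, truth = y2))
  if (inherits(x, "pred_set")) {
    x2 <- x[idx, ]
    x2$sample_id <- new_ids
    attr(x2, "model_id") <- ps_model_id(x)
    class(x2) <- c("pred_set", setdiff(class(x2), "pred_set"))
  } else if (inherits(x, "label_set")) {
    x2 <- label_set(new_ids, x$label[idx], ls_class_names(x))
  } else {
    abort("`x` must be a pred_set or label_set.")
  }
  list(x = x2, truth = y2)
}

# Built-in metric functions: f(pred_or_labels, truth) -> scalar.
builtin_metric <- function(name, n_bins = 15) {
  as_hard <- function(x) if (inherits(x, "pred_set")) hard_labels(x) else x
  switch(
    name,
    bacc = function(x, y) balanced_accuracy(confusion_matrix(y, as_hard(x))),
    auc_ovo = function(x, y) roc_auc_ovo(x, y),
    ece = function(x, y) ece(x, y, n_bins = n_bins),
    precision = function(x, y)
      weighted_ovr_metrics(confusion_matrix(y, as_hard(x)))$weighted$precision,
    recall = function(x, y)
      weighted_ovr_metrics(confusion_matrix(y, as_hard(x)))$weighted$recall,
    specificity = function(x, y)
      weighted_ovr_metrics(confusion_matrix(y, as_hard(x)))$weighted$specificity,
    f1 = function(x, y)
      weighted_ovr_metrics(confusion_matrix(y, as_hard(x)))$weighted$f1,
    abort(paste0("Unknown metric: ", name))
  )
}

#' Bootstrap a metric over resamples of the test set
#'
#' Evaluates a metric on R with-replacement resamples of the test
#' population and summarizes the replicate values by their mean and
#' percentile 95% confidence interval (2.5/97.5 percentiles of the
#' replicates). With a fixed seed the result is bit-reproducible.
#'
#' @param x A `pred_set` (probabilistic metrics) or `label_set`
#'   (label-only metrics such as balanced accuracy of a majority vote).
#' @param truth A `label_set` aligned by `sample_id`.
#' @param metric A metric name (`"bacc"`, `"auc_ovo"`, `"ece"`,
#'   `"precision"`, `"recall"`, `"specificity"`, `"f1"`) or a function
#'   `f(x, truth) -> scalar`.
#' @param R Number of replicates (default 100).
#' @param seed Integer seed (ignored when `indices` is given).
#' @param indices Optional precomputed [bootstrap_indices()], to share
#'   resampling noise across strategies.
#' @param metric_name Label stored in the summary; defaults to the
#'   metric string or `"custom"`.
#' @param n_bins Bin count forwarded to the ECE metric.
#' @return An object of class `bootstrap_summary` with the replicate
#'   values, mean, `ci_low`, `ci_high`, `R`, and `seed`. [tidy()] gives
#'   the replicates, [glance()] the one-row summary.
#' @export
bootstrap_metric <- function(x, truth, metric = "bacc", R = 100, seed = 1,
                             indices = NULL, metric_name = NULL, n_bins = 15) {
  stopifnot(inherits(truth, "label_set"))
  if (is.character(metric)) {
    metric_name <- metric_name %||% metric
    metric_fn <- builtin_metric(metric, n_bins = n_bins)
  } else {
    metric_name <- metric_name %||% "custom"
    metric_fn <- metric
  }
  if (is.null(indices)) {
    indices <- bootstrap_indices(truth, R = R, seed = seed)
  }
  R <- length(indices)
  if (R < 2) abort("Need R >= 2 replicates.")

  failures <- 0L
  vals <- purrr::map_dbl(indices, function(i) {
    pair <- resample_pair(x, truth, i)
    v <- tryCatch(
      suppressWarnings(metric_fn(pair$x, pair$truth)),
      error = function(e) NA_real_
    )
    if (is.na(v)) failures <<- failures + 1L
    v
  })
  if (failures > R / 2) {
    abort(sprintf(
      "Metric `%s` undefined on %d of %d replicates; aborting.",
      metric_name, failures, R))
  }
  if (failures > 0) {
    warn(sprintf("Metric `%s` undefined on %d replicate(s); dropped.",
                 metric_name, failures))
    vals <- vals[!is.na(vals)]
  }

  structure(
    list(
      metric_name = metric_name,
      replicates = vals,
      mean = mean(vals),
      ci_low = unname(quantile(vals, 0.025)),
      ci_high = unname(quantile(vals, 0.975)),
      R = length(vals),
      seed = as.integer(seed)
    ),
    class = "bootstrap_summary"
  )
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf("%s: mean %.3f [%.3f, %.3f] (R = %d)\n",
              x$metric_name, x$mean, x$ci_low, x$ci_high, x$R))
  invisible(x)
}

#' @rdname bootstrap_metric
#' @param ... Unused.
#' @export
tidy.bootstrap_summary <- function(x, ...) {
  tibble::tibble(metric = x$metric_name,
                 replicate = seq_along(x$replicates),
                 value = x$replicates)
}

#' @rdname bootstrap_metric
#' @export
glance.bootstrap_summary <- function(x, ...) {
  tibble::tibble(metric = x$metric_name, mean = x$mean,
                 ci_low = x$ci_low, ci_high = x$ci_high,
                 R = x$R, seed = x$seed)
}
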