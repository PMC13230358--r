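#' Two-tailed z-test between two bootstrap summaries
#'
#' Compares the bootstrap means of the same metric under two models:
#' `z = (mean_a - mean_b) / sqrt(s_a^2/R_a + s_b^2/R_b)` with `s` the
#' replicate standard deviation, and `p = 2 * (1 - Phi(|z|))`.
#' Significance codes follow the usual star convention:
#' `***` p < 0.001, `**` p < 0.01, `*` p < 0.05, `ns` otherwise.
#' With zero pooled variance the test degenerates: equal means give
#' z = 0, p = 1; unequal means give p = 0 with a warning.
#'
#' @param a,b `bootstrap_summary` objects for the same metric.
#' @return A one-row tibble: `metric`, `mean_a`, `mean_b`, `z`, `p`,
#'   `code`.
#' @export
z_compare <- function(a, b) {
  stopifnot(inherits(a, "bootstrap_summary"), inherits(b, "bootstrap_summary"))
  if (!identical(a$metric_name, b$metric_name)) {
    abort(sprintf("Metric mismatch: `%s` vs `%s`.", a$metric_name, b$metric_name))
  }
  if (a$R < 2 || b$R < 2) abort("Both summaries need R >= 2.")
  pooled <- sd(a$replicates)^2 / a$R + sd(b$replicates)^2 / b$R
  diff <- a$mean - b$mean
  if (pooled == 0) {
    if (diff == 0) {
      z <- 0
      p <- 1
    } else {
      warn("Degenerate comparison: zero variance with unequal means.")
      z <- sign(diff) * Inf
      p <- 0
    }
  } else {
    z <- diff / sqrt(pooled)
    p <- 2 * (1 - pnorm(abs(z)))
  }
  tibble::tibble(metric = a$metric_name, mean_a = a$mean, mean_b = b$mean,
                 z = z, p = p, code = signif_code(p))
}

#' @rdname z_compare
#' @param p A p-value (vectorized).
#' @export
signif_code <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Pearson chi-square test on a contingency table
#'
#' Classic test of association for categorical cohort characteristics
#' (e.g. sex by diagnosis): `chi2 = sum (O - E)^2 / E` with expected
#' counts from the row/column margins, `dof = (r-1)(c-1)`, no continuity
#' correction.
#'
#' @param counts A non-negative integer matrix with at least 2 rows and
#'   2 columns.
#' @return A one-row tibble: `chi2`, `dof`, `p`.
#' @examples
#' pearson_chi_square(rbind(c(132, 229), c(122, 100), c(41, 27)))
#' @export
pearson_chi_square <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    abort("Need at least a 2 x 2 table.")
  }
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    abort("Counts must be non-negative integers.")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort("Zero row or column margin: expected counts undefined.")
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  if (any(ct$expected <= 0)) abort("All expected cell counts must be > 0.")
  tibble::tibble(chi2 = unname(ct$statistic), dof = unname(ct$parameter),
                 p = ct$p.value)
}

#' Result-table comparison of bootstrap summaries with a reference model
#'
#' Builds the standard report layout for a group of models evaluated on
#' one metric: each row carries the bootstrap mean and 95% CI; the model
#' with the best mean (maximum for detection metrics, minimum for
#' calibration error) is marked `ref`, and every other model is
#' z-compared against it with a star code. Optionally appends an
#' "Average of means" row (used for base-model groups).
#'
#' @param summaries A named list of `bootstrap_summary` objects sharing
#'   one metric.
#' @param minimize `TRUE` when smaller is better (e.g. ECE).
#' @param average_of_means Append the group average row?
#' @return A tibble: `model`, `metric`, `mean`, `ci_low`, `ci_high`,
#'   `z`, `p`, `code` (`"ref"` on the reference row).
#' @export
comparison_table <- function(summaries, minimize = FALSE,
                             average_of_means = FALSE) {
  if (length(summaries) < 1) abort("Need at least one summary.")
  nms <- names(summaries) %||% paste0("model_", seq_along(summaries))
  names(summaries) <- nms
  metric <- summaries[[1]]$metric_name
  purrr::walk(summaries, function(s) {
    if (!identical(s$metric_name, metric)) {
      abort("All summaries must share one metric.")
    }
  })
  means <- purrr::map_dbl(summaries, "mean")
  ref <- if (minimize) which.min(means) else which.max(means)

  rows <- purrr::imap(summaries, function(s, i) {
    pos <- match(i, nms)
    if (pos == ref || length(summaries) == 1) {
      tibble::tibble(model = i, metric = metric, mean = s$mean,
                     ci_low = s$ci_low, ci_high = s$ci_high,
                     z = NA_real_, p = NA_real_, code = "ref")
    } else {
      zc <- z_compare(s, summaries[[ref]])
      tibble::tibble(model = i, metric = metric, mean = s$mean,
                     ci_low = s$ci_low, ci_high = s$ci_high,
                     z = zc$z, p = zc$p, code = zc$code)
    }
  })
  out <- dplyr::bind_rows(rows)
  if (length(summaries) == 1) out$code <- "ref"
  if (average_of_means) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      model = "Average of means", metric = metric, mean = mean(means),
      ci_low = NA_real_, ci_high = NA_real_,
      z = NA_real_, p = NA_real_, code = NA_character_
    ))
  }
  out
}
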