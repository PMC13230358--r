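#' Majority vote over base-model hard labels
#'
#' Combines discrete class decisions — not probabilities — from m base
#' models: each sample is assigned the class with most votes. Vote ties
#' are broken by the lowest class index (the same rule used for argmax
#' ties in [hard_labels()]); the number of tied samples is reported with
#' a message. Because the inputs are hard labels, majority-vote
#' ensembles carry no probability information, so ROC AUC and expected
#' calibration error are undefined for them.
#'
#' @param label_sets A list of m `label_set` objects on the same samples
#'   (alignment is by `sample_id`).
#' @return A `label_set` with the voted class per sample.
#' @export
majority_vote <- function(label_sets) {
  if (length(label_sets) < 1) abort("Need at least one label set.")
  purrr::walk(label_sets, function(s) {
    if (!inherits(s, "label_set")) abort("All inputs must be label sets.")
  })
  sets <- align_sets(label_sets)
  cls <- ls_class_names(sets[[1]])
  K <- length(cls)
  votes <- do.call(cbind, purrr::map(sets, "label")) # n x m, 0-based
  counts <- t(apply(votes, 1, function(v) tabulate(v + 1L, nbins = K)))
  winner <- max.col(counts, ties.method = "first") - 1L
  n_tied <- sum(apply(counts, 1, function(ct) sum(ct == max(ct)) > 1))
  if (n_tied > 0) {
    inform(sprintf(
      "majority_vote: %d sample(s) had tied votes; lowest class index used.",
      n_tied))
  }
  label_set(sets[[1]]$sample_id, winner, cls)
}

#' Average base-model softmax probabilities (unweighted or weighted)
#'
#' Forms the per-sample convex combination of the base models' class
#' probability rows. With `weights = NULL` all models get weight `1/m`
#' (the unweighted average); otherwise `weights` must be non-negative
#' and sum to 1 (tolerance 1e-9). Because each row is a convex
#' combination of probability vectors, output rows sum to 1 by
#' construction. Final hard decisions follow by [hard_labels()].
#'
#' @param pred_sets A list of m `pred_set` objects on the same samples
#'   and classes (aligned by `sample_id` and class name).
#' @param weights Optional numeric m-vector of model weights, e.g.
#'   `ensemble_weights(bacc)$w`.
#' @param model_id Tag for the combined set.
#' @return A `pred_set` with the combined probabilities.
#' @examples
#' a <- prediction_set(data.frame(sample_id = "s", A = 0.6, B = 0.3, C = 0.1))
#' b <- prediction_set(data.frame(sample_id = "s", A = 0.2, B = 0.5, C = 0.3))
#' average_combine(list(a, b))                       # (0.4, 0.4, 0.2)
#' average_combine(list(a, b), weights = c(0.25, 0.75)) # (0.3, 0.45, 0.25)
#' @export
average_combine <- function(pred_sets, weights = NULL, model_id = "ensemble") {
  m <- length(pred_sets)
  if (m < 1) abort("Need at least one prediction set.")
  purrr::walk(pred_sets, function(s) {
    if (!inherits(s, "pred_set")) abort("All inputs must be prediction sets.")
  })
  if (is.null(weights)) {
    weights <- rep(1 / m, m)
  } else {
    if (length(weights) != m) {
      abort(sprintf("Got %d weights for %d models.", length(weights), m))
    }
    if (anyNA(weights) || any(weights < 0)) {
      abort("Weights must be non-negative.")
    }
    if (abs(sum(weights) - 1) > 1e-9) {
      abort(sprintf("Weights must sum to 1 (got %.12f).", sum(weights)))
    }
  }
  sets <- align_sets(pred_sets)
  probs <- Reduce(`+`, purrr::map2(sets, weights, ~ ps_probs(.x) * .y))
  out <- tibble::as_tibble(as.data.frame(probs))
  out <- dplyr::bind_cols(tibble::tibble(sample_id = sets[[1]]$sample_id), out)
  prediction_set(out, model_id = model_id)
}
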