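#' Rank base models by validation balanced accuracy
#'
#' Ranks run from 1 (weakest) to m (strongest). Ties are broken by input
#' position: the earlier model receives the lower rank, so ranking is
#' deterministic and seed-free.
#'
#' @param bacc Numeric vector of m balanced accuracies in `[0, 1]`.
#' @return Integer vector of ranks, a permutation of `1..m`.
#' @examples
#' rank_models(c(0.527, 0.729, 0.728, 0.526, 0.600)) # 2 5 4 1 3
#' @export
rank_models <- function(bacc) {
  if (length(bacc) < 1) abort("Need at least one balanced accuracy.")
  if (anyNA(bacc)) abort("Balanced accuracies must not be NA.")
  if (any(bacc < 0 | bacc > 1)) abort("Balanced accuracies must lie in [0, 1].")
  as.integer(rank(bacc, ties.method = "first"))
}

#' Rank-squared balanced-accuracy ensemble weights
#'
#' Derives normalized base-model weights for weighted softmax averaging
#' from cross-validation validation balanced accuracies. With
#' `beta = min(bacc)` and ranks `1..m` ascending in balanced accuracy,
#' each model's multiplication factor is
#' `alpha_j = (bacc_j - beta + 1) * rank_j^2`, and the weights are the
#' normalized factors `w_j = alpha_j / sum(alpha)`. The `+ 1` constant
#' keeps every weight strictly positive, so even the weakest model
#' contributes; the squared rank widens the spread in favour of stronger
#' models. The weakest model (rank 1, no ties) always has `alpha = 1`.
#'
#' Balanced accuracies are expected to come from held-out validation
#' folds, not from the test set. Weights are kept at full precision
#' internally; round only for display.
#'
#' @param bacc Numeric vector of m validation balanced accuracies.
#' @param model_ids Optional model tags (default `model_1..model_m`).
#' @return An object of class `ensemble_weights`: a list with elements
#'   `model_ids`, `bacc`, `rank`, `beta`, `alpha`, `w`, and `m`. Use
#'   [tidy()] for a per-model tibble and [glance()] for the scalars.
#' @examples
#' w <- ensemble_weights(c(0.485, 0.704, 0.635, 0.734, 0.783))
#' round(w$w, 3) # 0.014 0.159 0.067 0.290 0.470
#' tidy(w)
#' @export
ensemble_weights <- function(bacc, model_ids = NULL) {
  if (length(bacc) < 1) abort("Need at least one balanced accuracy.")
  if (anyNA(bacc)) abort("Balanced accuracies must not be NA.")
  m <- length(bacc)
  model_ids <- model_ids %||% paste0("model_", seq_len(m))
  if (length(model_ids) != m) abort("`model_ids` must have length m.")
  r <- rank_models(bacc)
  beta <- min(bacc)
  alpha <- (bacc - beta + 1) * r^2
  w <- alpha / sum(alpha)
  structure(
    list(model_ids = as.character(model_ids), bacc = as.numeric(bacc),
         rank = r, beta = beta, alpha = alpha, w = w, m = m),
    class = "ensemble_weights"
  )
}

#' @export
print.ensemble_weights <- function(x, ...) {
  cat(sprintf("Ensemble weights (m = %d, beta = %.3f)\n", x$m, x$beta))
  print(tidy(x), ...)
  invisible(x)
}

#' @rdname ensemble_weights
#' @param x An `ensemble_weights` object.
#' @param ... Unused.
#' @export
tidy.ensemble_weights <- function(x, ...) {
  tibble::tibble(model_id = x$model_ids, bacc = x$bacc, rank = x$rank,
                 alpha = x$alpha, weight = x$w)
}

#' @rdname ensemble_weights
#' @export
glance.ensemble_weights <- function(x, ...) {
  tibble::tibble(m = x$m, beta = x$beta, alpha_sum = sum(x$alpha),
                 weight_sum = sum(x$w))
}
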