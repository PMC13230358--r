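#' Build a prediction set from a data frame of class probabilities
#'
#' A prediction set holds one base model's softmax output on a test set:
#' one row per sample, one numeric column per class, plus a sample-id
#' column. Rows must be proper probability vectors. Row sums that are off
#' by more than 1e-4 are rejected; sums off by between 1e-6 and 1e-4
#' (typical float round-trip noise) are silently renormalized with a
#' warning.
#'
#' @param data A data frame with a sample-id column and K >= 2 numeric
#'   class-probability columns.
#' @param id_col Name of the sample-id column. Default `"sample_id"`.
#' @param class_cols Names of the class-probability columns, in class
#'   order. Default: every column except `id_col`.
#' @param model_id A short tag identifying the model that produced the
#'   probabilities.
#'
#' @return A tibble of class `pred_set` with columns `sample_id` and one
#'   column per class, carrying `model_id` as an attribute. Class order is
#'   the column order; use [ps_class_names()] to read it back.
#' @examples
#' prediction_set(
#'   data.frame(sample_id = c("a", "b"), CN = c(0.7, 0.2),
#'              MCI = c(0.2, 0.5), AD = c(0.1, 0.3)),
#'   model_id = "m1"
#' )
#' @export
prediction_set <- function(data, id_col = "sample_id", class_cols = NULL,
                           model_id = "model") {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  if (!id_col %in% names(data)) {
    abort(paste0("Missing sample-id column `", id_col, "`."))
  }
  class_cols <- class_cols %||% setdiff(names(data), id_col)
  missing <- setdiff(class_cols, names(data))
  if (length(missing) > 0) {
    abort(paste0("Missing class columns: ", paste(missing, collapse = ", ")))
  }
  if (length(class_cols) < 2) abort("A prediction set needs K >= 2 classes.")
  if (anyDuplicated(class_cols)) abort("Class names must be distinct.")

  ids <- as.character(data[[id_col]])
  if (length(ids) < 1) abort("A prediction set needs at least one sample.")
  if (anyDuplicated(ids)) abort("Sample ids must be unique.")
  if (anyNA(ids)) abort("Sample ids must not be missing.")

  probs <- as.matrix(data[class_cols])
  storage.mode(probs) <- "double"
  if (anyNA(probs)) abort("Probabilities must not be missing.")
  if (any(probs < 0) || any(probs > 1)) {
    abort("All probabilities must lie in [0, 1].")
  }
  dev <- abs(rowSums(probs) - 1)
  if (any(dev > 1e-4)) {
    bad <- which(dev > 1e-4)[1]
    abort(sprintf(
      "Row %d sums to %.6f; probability rows must sum to 1 (tolerance 1e-4).",
      bad, sum(probs[bad, ])
    ))
  }
  fix <- dev > 1e-6
  if (any(fix)) {
    warn(sprintf("Renormalized %d row(s) with sums off by <= 1e-4.", sum(fix)))
    probs[fix, ] <- probs[fix, ] / rowSums(probs[fix, , drop = FALSE])
  }

  out <- tibble::tibble(sample_id = ids)
  for (k in seq_along(class_cols)) out[[class_cols[k]]] <- probs[, k]
  attr(out, "model_id") <- as.character(model_id)
  class(out) <- c("pred_set", class(out))
  out
}

#' Class names, probability matrix, and model id of a prediction set
#'
#' @param ps A `pred_set`.
#' @return `ps_class_names()`: character vector of class labels in class
#'   order. `ps_probs()`: the n x K probability matrix with sample ids as
#'   row names. `ps_model_id()`: the model tag.
#' @export
ps_class_names <- function(ps) {
  stopifnot(inherits(ps, "pred_set"))
  setdiff(names(ps), "sample_id")
}

#' @rdname ps_class_names
#' @export
ps_probs <- function(ps) {
  stopifnot(inherits(ps, "pred_set"))
  m <- as.matrix(ps[ps_class_names(ps)])
  rownames(m) <- ps$sample_id
  m
}

#' @rdname ps_class_names
#' @export
ps_model_id <- function(ps) attr(ps, "model_id") %||% "model"

#' Read and write prediction sets as delimited text
#'
#' The file layout is `sample_id,<class1>,...,<classK>` with one row per
#' sample. Writing uses full float precision so that a write/read
#' round trip reproduces probabilities to better than 1e-12. When
#' `class_names` is supplied the file's class columns are re-indexed to
#' that order by name; class names absent from the file are an error.
#'
#' @param path File path.
#' @param delim Field delimiter, `","` (CSV) or `"\t"` (TSV).
#' @param model_id Model tag for the returned set; defaults to the file
#'   name without extension.
#' @param class_names Optional enforced class order.
#' @return `read_prediction_set()` returns a validated [prediction_set()];
#'   `write_prediction_set()` returns `path` invisibly.
#' @export
read_prediction_set <- function(path, delim = ",", model_id = NULL,
                                class_names = NULL) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  # base-R parser: correctly rounded doubles, so write/read round-trips
  # to the last bit
  df <- utils::read.delim(path, sep = delim, check.names = FALSE,
                          stringsAsFactors = FALSE)
  model_id <- model_id %||% tools::file_path_sans_ext(basename(path))
  ps <- prediction_set(df, model_id = model_id)
  if (!is.null(class_names)) {
    missing <- setdiff(class_names, ps_class_names(ps))
    if (length(missing) > 0) {
      abort(paste0("File ", path, " lacks class column(s): ",
                   paste(missing, collapse = ", ")))
    }
    ps <- ps[c("sample_id", class_names)]
    class(ps) <- c("pred_set", setdiff(class(ps), "pred_set"))
    attr(ps, "model_id") <- model_id
  }
  ps
}

#' @rdname read_prediction_set
#' @param ps A `pred_set` to serialize.
#' @export
write_prediction_set <- function(ps, path, delim = ",") {
  stopifnot(inherits(ps, "pred_set"))
  if (length(ps_class_names(ps)) < 1) abort("Prediction set has no classes.")
  df <- as.data.frame(ps)
  # repr-round-trippable floats
  for (nm in ps_class_names(ps)) {
    df[[nm]] <- formatC(df[[nm]], format = "g", digits = 17)
  }
  readr::write_delim(df, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Hard labels: per-sample argmax class of a prediction set
#'
#' Converts softmax probabilities to discrete class decisions. Ties are
#' broken deterministically by the lowest class index.
#'
#' @param ps A `pred_set`.
#' @return A `label_set` tibble with columns `sample_id`, `label`
#'   (0-based class index), and `class` (class name), carrying the class
#'   names as an attribute.
#' @export
hard_labels <- function(ps) {
  stopifnot(inherits(ps, "pred_set"))
  probs <- ps_probs(ps)
  idx <- max.col(probs, ties.method = "first")
  label_set(ps$sample_id, idx - 1L, ps_class_names(ps))
}

#' Construct a label set
#'
#' @param sample_id Character vector of unique sample ids.
#' @param label Integer class indices, 0-based (`0 .. K-1`).
#' @param class_names Ordered class labels.
#' @return A tibble of class `label_set` with columns `sample_id`,
#'   `label`, `class`.
#' @export
label_set <- function(sample_id, label, class_names) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) abort("Sample ids must be unique.")
  label <- as.integer(label)
  K <- length(class_names)
  if (anyNA(label) || any(label < 0L) || any(label >= K)) {
    abort(sprintf("Labels must be integers in 0..%d.", K - 1L))
  }
  out <- tibble::tibble(sample_id = sample_id, label = label,
                        class = class_names[label + 1L])
  attr(out, "class_names") <- class_names
  class(out) <- c("label_set", class(out))
  out
}

#' @rdname label_set
#' @param x A `label_set`.
#' @export
ls_class_names <- function(x) {
  stopifnot(inherits(x, "label_set"))
  attr(x, "class_names")
}

#' Read and write ground-truth label files
#'
#' Labels files have columns `sample_id,label` with 0-based integer class
#' indices.
#'
#' @param path File path.
#' @param class_names Ordered class labels giving meaning to the indices.
#' @param delim Field delimiter.
#' @return A `label_set` (reader) or `path` invisibly (writer).
#' @export
read_labels <- function(path, class_names, delim = ",") {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  df <- utils::read.delim(path, sep = delim, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "label") %in% names(df))) {
    abort("Labels file must have columns sample_id,label.")
  }
  label_set(df$sample_id, df$label, class_names)
}

#' @rdname read_labels
#' @param labels A `label_set`.
#' @export
write_labels <- function(labels, path, delim = ",") {
  stopifnot(inherits(labels, "label_set"))
  readr::write_delim(labels[c("sample_id", "label")], path, delim = delim,
                     progress = FALSE)
  invisible(path)
}

# Align a list of pred_sets (or label_sets) onto the id order and class
# order of the first; alignment is by sample_id, never by row position.
align_sets <- function(sets) {
  stopifnot(length(sets) >= 1)
  ref_ids <- sets[[1]]$sample_id
  purrr::map(sets, function(s) {
    if (!setequal(s$sample_id, ref_ids) ||
        length(s$sample_id) != length(ref_ids)) {
      abort("Sets are not aligned: sample ids differ.")
    }
    s2 <- s[match(ref_ids, s$sample_id), ]
    if (inherits(s, "pred_set")) {
      ref_cls <- ps_class_names(sets[[1]])
      missing <- setdiff(ref_cls, ps_class_names(s))
      if (length(missing) > 0) {
        abort(paste0("Class name(s) missing from model ", ps_model_id(s),
                     ": ", paste(missing, collapse = ", ")))
      }
      s2 <- s2[c("sample_id", ref_cls)]
      attr(s2, "model_id") <- ps_model_id(s)
      class(s2) <- c("pred_set", setdiff(class(s2), "pred_set"))
    }
    if (inherits(s, "label_set")) {
      attr(s2, "class_names") <- ls_class_names(s)
      class(s2) <- c("label_set", setdiff(class(s2), "label_set"))
    }
    s2
  })
}
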