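#' Build or read a subject-level cohort table
#'
#' A cohort table carries one row per subject with diagnosis, sex, and
#' age in whole years — the three factors used for stratified splitting.
#' Fractional ages are floored to integer years (with a message), since
#' age bins are defined on whole years.
#'
#' @param data A data frame with columns `subject_id`, `diagnosis`,
#'   `sex`, `age` (extra covariate columns are kept).
#' @param class_names Optional ordered diagnosis levels; defaults to the
#'   order of first appearance.
#' @return A tibble of class `cohort_table`.
#' @export
cohort_table <- function(data, class_names = NULL) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  need <- c("subject_id", "diagnosis", "sex", "age")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    abort(paste0("Missing cohort column(s): ", paste(missing, collapse = ", ")))
  }
  out <- tibble::as_tibble(data)
  out$subject_id <- as.character(out$subject_id)
  if (anyDuplicated(out$subject_id)) abort("Duplicate subject_id.")
  age <- suppressWarnings(as.numeric(out$age))
  if (anyNA(age)) abort("Unparseable age value(s).")
  if (any(age < 0)) abort("Ages must be >= 0.")
  if (any(age != floor(age))) {
    inform(sprintf("Floored %d fractional age(s) to integer years.",
                   sum(age != floor(age))))
  }
  out$age <- as.integer(floor(age))
  out$diagnosis <- as.character(out$diagnosis)
  class_names <- class_names %||% unique(out$diagnosis)
  unknown <- setdiff(out$diagnosis, class_names)
  if (length(unknown) > 0) {
    abort(paste0("Diagnosis value(s) outside the class set: ",
                 paste(unknown, collapse = ", ")))
  }
  out$sex <- as.character(out$sex)
  attr(out, "class_names") <- class_names
  class(out) <- c("cohort_table", class(out))
  out
}

#' @rdname cohort_table
#' @param path File path of a delimited cohort file with columns
#'   `subject_id,diagnosis,sex,age`.
#' @param delim Field delimiter.
#' @export
read_cohort <- function(path, delim = ",", class_names = NULL) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  df <- utils::read.delim(path, sep = delim, check.names = FALSE,
                          stringsAsFactors = FALSE)
  cohort_table(df, class_names = class_names)
}

#' @rdname cohort_table
#' @param cohort A `cohort_table`.
#' @export
write_cohort <- function(cohort, path, delim = ",") {
  stopifnot(inherits(cohort, "cohort_table"))
  readr::write_delim(as.data.frame(cohort), path, delim = delim,
                     progress = FALSE)
  invisible(path)
}

#' Ground-truth labels of a cohort
#'
#' @param cohort A `cohort_table`.
#' @return A `label_set` keyed by `subject_id`, with 0-based diagnosis
#'   indices in the cohort's class order.
#' @export
cohort_labels <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  cls <- attr(cohort, "class_names")
  label_set(cohort$subject_id, match(cohort$diagnosis, cls) - 1L, cls)
}
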