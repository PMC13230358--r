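#' Configure an end-to-end ensemble evaluation experiment
#'
#' An experiment evaluates m base models and up to three ensemble
#' decision strategies (majority vote, unweighted average, weighted
#' average) on one test set, with bootstrap confidence intervals,
#' reference-model z-test comparisons, and reliability diagrams.
#'
#' Inputs come either from files (`pred_files` + `labels_file`) or from
#' the synthetic generator (`synthetic`). Weights for the weighted
#' average come from held-out validation balanced accuracies: pass them
#' in `validation_bacc`, or (synthetic inputs only) leave `NULL` to
#' derive them from a generated validation cohort.
#'
#' @param synthetic A [synthetic_config()], or `NULL` when reading
#'   files.
#' @param pred_files Character vector of per-model prediction CSVs.
#' @param labels_file Ground-truth labels CSV.
#' @param class_names Class order for file inputs.
#' @param validation_bacc Per-model validation balanced accuracies.
#' @param strategies Subset of `c("majority", "unweighted", "weighted")`.
#' @param metrics Subset of the built-in metric names; ECE and ROC AUC
#'   are automatically dropped for the majority vote.
#' @param R Bootstrap replicates.
#' @param n_bins Reliability-diagram bins.
#' @param test_fraction Test share for the synthetic stratified split.
#' @param seed Master seed.
#' @return A validated list of class `experiment_config`.
#' @export
experiment_config <- function(synthetic = synthetic_config(),
                              pred_files = NULL, labels_file = NULL,
                              class_names = NULL,
                              validation_bacc = NULL,
                              strategies = c("majority", "unweighted", "weighted"),
                              metrics = c("bacc", "auc_ovo", "ece"),
                              R = 100, n_bins = 15,
                              test_fraction = 0.2, seed = 1) {
  strategies <- match.arg(strategies, several.ok = TRUE)
  if (length(strategies) < 1) abort("Need at least one strategy.")
  from_files <- !is.null(pred_files)
  if (from_files && is.null(labels_file)) {
    abort("File inputs need both `pred_files` and `labels_file`.")
  }
  if (!from_files && is.null(synthetic)) {
    abort("Provide either `synthetic` or `pred_files` + `labels_file`.")
  }
  if ("weighted" %in% strategies && from_files && is.null(validation_bacc)) {
    abort("The weighted strategy needs `validation_bacc` for file inputs.")
  }
  structure(
    list(synthetic = synthetic, pred_files = pred_files,
         labels_file = labels_file, class_names = class_names,
         validation_bacc = validation_bacc, strategies = strategies,
         metrics = metrics, R = as.integer(R), n_bins = as.integer(n_bins),
         test_fraction = test_fraction, seed = as.integer(seed)),
    class = "experiment_config"
  )
}

#' Run a full ensemble evaluation experiment
#'
#' Produces the standard report bundle: (1) a base-model table with
#' per-model bootstrap mean/CI for every metric, reference marking,
#' z-test star codes, and an "Average of means" row; (2) an ensemble
#' table for the requested decision strategies, with ECE and ROC AUC
#' left out for the majority vote (hard labels carry no probabilities);
#' (3) the weights table (validation balanced accuracy, rank, weight);
#' (4) reliability diagrams for both averaging strategies. All
#' randomness flows from the config seed, and the same bootstrap index
#' sets are reused for every model and strategy so comparisons share
#' resampling noise; rerunning with the same config is bit-identical.
#'
#' @param cfg An [experiment_config()].
#' @return An object of class `experiment_report` with elements
#'   `base_table`, `ensemble_table`, `weights`, `reliability`,
#'   `summaries`, `test_labels`, `n_test`, and `config`.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))

  if (!is.null(cfg$pred_files)) {
    if (is.null(cfg$class_names)) abort("File inputs need `class_names`.")
    preds <- purrr::imap(cfg$pred_files, function(f, i) {
      read_prediction_set(f, class_names = cfg$class_names,
                          model_id = paste0("model_", i))
    })
    names(preds) <- paste0("model_", seq_along(preds))
    truth <- read_labels(cfg$labels_file, cfg$class_names)
    val_bacc <- cfg$validation_bacc
  } else {
    sc <- cfg$synthetic
    cohort <- generate_cohort(sc)
    split <- stratified_split(cohort, test_fraction = cfg$test_fraction,
                              seed = sc$seed + 1L)
    labels_all <- cohort_labels(cohort)
    truth <- labels_all[labels_all$sample_id %in% split$test_ids, ]
    attr(truth, "class_names") <- sc$class_names
    class(truth) <- c("label_set", setdiff(class(truth), "label_set"))
    preds <- generate_base_predictions(truth, sc)
    val_bacc <- cfg$validation_bacc
    if (is.null(val_bacc) && "weighted" %in% cfg$strategies) {
      val_truth <- labels_all[labels_all$sample_id %in% split$train_ids, ]
      attr(val_truth, "class_names") <- sc$class_names
      class(val_truth) <- c("label_set", setdiff(class(val_truth), "label_set"))
      val_preds <- generate_base_predictions(val_truth, sc,
                                             seed_offset = 500009L)
      val_bacc <- purrr::map_dbl(val_preds, function(p) {
        balanced_accuracy(confusion_matrix(val_truth, hard_labels(p)))
      })
    }
  }
  m <- length(preds)

  weights <- NULL
  if ("weighted" %in% cfg$strategies) {
    weights <- ensemble_weights(val_bacc, model_ids = names(preds))
  }

  ensembles <- list()
  if ("majority" %in% cfg$strategies) {
    ensembles[["Majority vote"]] <- majority_vote(purrr::map(preds, hard_labels))
  }
  if ("unweighted" %in% cfg$strategies) {
    ensembles[["Unweighted average"]] <-
      average_combine(preds, model_id = "unweighted_average")
  }
  if ("weighted" %in% cfg$strategies) {
    ensembles[["Weighted average"]] <-
      average_combine(preds, weights = weights$w, model_id = "weighted_average")
  }

  idx <- bootstrap_indices(truth, R = cfg$R, seed = cfg$seed)

  boot_all <- function(x, metric) {
    bootstrap_metric(x, truth, metric = metric, indices = idx,
                     seed = cfg$seed, n_bins = cfg$n_bins)
  }
  prob_only <- c("auc_ovo", "ece")

  base_summaries <- purrr::map(cfg$metrics, function(met) {
    purrr::map(preds, boot_all, metric = met)
  })
  names(base_summaries) <- cfg$metrics
  base_table <- dplyr::bind_rows(purrr::map(cfg$metrics, function(met) {
    comparison_table(base_summaries[[met]], minimize = met == "ece",
                     average_of_means = TRUE)
  }))

  ens_summaries <- purrr::map(cfg$metrics, function(met) {
    usable <- ensembles
    if (met %in% prob_only) {
      usable <- usable[!purrr::map_lgl(usable, inherits, "label_set")]
    }
    if (length(usable) == 0) return(NULL)
    purrr::map(usable, boot_all, metric = met)
  })
  names(ens_summaries) <- cfg$metrics
  ensemble_table <- dplyr::bind_rows(purrr::map(cfg$metrics, function(met) {
    if (is.null(ens_summaries[[met]])) return(NULL)
    comparison_table(ens_summaries[[met]], minimize = met == "ece")
  }))

  reliability_out <- purrr::map(
    ensembles[!purrr::map_lgl(ensembles, inherits, "label_set")],
    function(e) reliability(e, truth, n_bins = cfg$n_bins)
  )

  structure(
    list(base_table = base_table, ensemble_table = ensemble_table,
         weights = weights, reliability = reliability_out,
         summaries = list(base = base_summaries, ensemble = ens_summaries),
         test_labels = truth, n_test = nrow(truth), config = cfg),
    class = "experiment_report"
  )
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("Experiment report: %d base models, %d test samples, R = %d\n\n",
              length(unique(setdiff(x$base_table$model, "Average of means"))),
              x$n_test, x$config$R))
  cat("Base models:\n")
  print(round_display(x$base_table))
  cat("\nEnsembles:\n")
  print(round_display(x$ensemble_table))
  if (!is.null(x$weights)) {
    cat("\n")
    print(x$weights)
  }
  invisible(x)
}

# Display-rounded twin of a report table (3 decimals, full precision kept
# in the underlying object).
round_display <- function(tbl) {
  dplyr::mutate(tbl, dplyr::across(dplyr::where(is.numeric), ~ round(.x, 3)))
}

#' Serialize an experiment report to JSON and Markdown
#'
#' Writes `report.json` (full precision) and `report.md`
#' (display-rounded to 3 decimals) into `dir`.
#'
#' @param report An `experiment_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "experiment_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  payload <- list(
    base_table = report$base_table,
    ensemble_table = report$ensemble_table,
    weights = if (!is.null(report$weights)) {
      c(as.list(tidy(report$weights)),
        list(beta = report$weights$beta, m = report$weights$m))
    },
    reliability = purrr::map(report$reliability, function(r) {
      list(bins = r$bins, ece = r$ece, n = r$n, scheme = r$scheme)
    }),
    n_test = report$n_test,
    R = report$config$R,
    seed = report$config$seed
  )
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")

  md <- c(
    "# Ensemble evaluation report", "",
    sprintf("Test samples: %d; bootstrap replicates: %d; seed: %d.",
            report$n_test, report$config$R, report$config$seed), "",
    "## Base models", "", md_table(round_display(report$base_table)), "",
    "## Ensembles", "", md_table(round_display(report$ensemble_table))
  )
  if (!is.null(report$weights)) {
    md <- c(md, "", "## Weights", "",
            md_table(round_display(tidy(report$weights))))
  }
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}

md_table <- function(df) {
  cells <- purrr::map(df, function(col) {
    out <- as.character(col)
    out[is.na(out)] <- ""
    out
  })
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  rule <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- purrr::pmap_chr(cells, function(...) {
    paste0("| ", paste(c(...), collapse = " | "), " |")
  })
  c(header, rule, rows)
}
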