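#' Configuration for the synthetic three-class study
#'
#' Defines the generative conditions for a synthetic diagnostic cohort
#' and a bank of base-model softmax outputs. The defaults emulate an
#' imbalanced three-class memory-clinic study: 651 subjects split
#' roughly 361/222/68 across cognitively normal (CN), mild cognitive
#' impairment (MCI), and Alzheimer's disease (AD); per-class female
#' proportions 63.4%/45.0%/39.7%; per-class normal ages
#' (69.5 +/- 6.7, 71.9 +/- 7.6, 74.4 +/- 7.9 years) clipped to 50-90
#' and rounded to whole years; and m = 5 base models, one per
#' cross-validation fold.
#'
#' Base-model predictions follow a logit-noise model: for sample i with
#' true class k, model j sees logits
#' `signal_j * onehot(k) + N(0, 1)` per class and emits
#' `softmax(logits / temperature_j)`. `signal` controls accuracy
#' (0 = chance, large = near-perfect); `temperature` controls
#' calibration independently of the decision (1 = calibrated in shape,
#' < 1 over-confident, > 1 under-confident). The default model bank is
#' heterogeneous in both dials, mimicking fold-to-fold variability.
#'
#' @param n_subjects Cohort size.
#' @param class_names Ordered diagnosis labels.
#' @param class_proportions Class mixing proportions (sum to 1).
#' @param female_proportion Per-class probability of female sex.
#' @param age_mean,age_sd Per-class age distribution (years).
#' @param age_range Two-element clipping range for ages (years).
#' @param m_models Number of base models.
#' @param signal Per-model correct-class logit separation (length
#'   `m_models`).
#' @param temperature Per-model softmax temperature (> 0, length
#'   `m_models`).
#' @param seed Integer master seed for all draws.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 651,
                             class_names = c("CN", "MCI", "AD"),
                             class_proportions = c(361, 222, 68) / 651,
                             female_proportion = c(0.634, 0.450, 0.397),
                             age_mean = c(69.50, 71.91, 74.37),
                             age_sd = c(6.74, 7.57, 7.94),
                             age_range = c(50, 90),
                             m_models = 5,
                             signal = c(0.6, 1.0, 1.4, 1.8, 2.2),
                             temperature = c(0.5, 0.8, 1.0, 1.3, 1.6),
                             seed = 1) {
  K <- length(class_names)
  stopifnot(K >= 2, n_subjects >= 1)
  if (length(class_proportions) != K ||
      abs(sum(class_proportions) - 1) > 1e-9) {
    abort("`class_proportions` must be K probabilities summing to 1.")
  }
  stopifnot(length(female_proportion) == K,
            length(age_mean) == K, length(age_sd) == K,
            length(age_range) == 2, age_range[1] < age_range[2])
  m_models <- as.integer(m_models)
  if (m_models < 1) abort("Need m_models >= 1.")
  if (length(signal) != m_models || any(signal < 0)) {
    abort("`signal` must be m_models non-negative values.")
  }
  if (length(temperature) != m_models || any(temperature <= 0)) {
    abort("`temperature` must be m_models positive values.")
  }
  structure(
    list(n_subjects = as.integer(n_subjects), class_names = class_names,
         class_proportions = class_proportions,
         female_proportion = female_proportion,
         age_mean = age_mean, age_sd = age_sd, age_range = age_range,
         m_models = m_models, signal = signal, temperature = temperature,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Five-year age bins with open-ended extremes
#'
#' Bin 1: <= 64 years; bin 2: 65-69; bin 3: 70-74; bin 4: 75-80;
#' bin 5: >= 81. The outer bins are open-ended so the extreme ages keep
#' enough subjects per stratum.
#'
#' @param age Integer ages in years (vectorized), `>= 0`.
#' @return Integer bin indices 1..5.
#' @examples
#' assign_age_bin(c(64, 65, 80, 81)) # 1 2 4 5
#' @export
assign_age_bin <- function(age) {
  if (anyNA(age) || any(age < 0)) abort("Ages must be >= 0.")
  findInterval(age, c(65, 70, 75, 81)) + 1L
}

#' Generate a synthetic diagnostic cohort
#'
#' Draws diagnosis, sex, and age per subject according to the config:
#' diagnosis from the class proportions, sex from the per-class female
#' proportion, age from the per-class normal distribution clipped to
#' the configured range and rounded to whole years. Fully reproducible
#' per seed.
#'
#' @param cfg A [synthetic_config()].
#' @return A `cohort_table` with columns `subject_id`, `diagnosis`,
#'   `sex`, `age`; ground-truth labels via [cohort_labels()].
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n <- cfg$n_subjects
  K <- length(cfg$class_names)
  withr::with_seed(cfg$seed, {
    cls_idx <- sample.int(K, n, replace = TRUE, prob = cfg$class_proportions)
    sex <- ifelse(
      stats::runif(n) < cfg$female_proportion[cls_idx], "F", "M")
    age <- round(pmin(pmax(
      rnorm(n, cfg$age_mean[cls_idx], cfg$age_sd[cls_idx]),
      cfg$age_range[1]), cfg$age_range[2]))
    cohort_table(
      tibble::tibble(
        subject_id = sprintf("S%05d", seq_len(n)),
        diagnosis = cfg$class_names[cls_idx],
        sex = sex,
        age = as.integer(age)
      ),
      class_names = cfg$class_names
    )
  })
}

#' Generate base-model softmax predictions for labeled samples
#'
#' For each of the config's m models, draws per-class logits
#' `signal_j * onehot(true class) + N(0, 1)` and emits
#' `softmax(logits / temperature_j)`. Each model uses an independent
#' stream derived deterministically from the master seed and the model
#' index, so the bank is reproducible and individual models can be
#' regenerated in isolation.
#'
#' @param truth A `label_set` of ground-truth classes.
#' @param cfg A [synthetic_config()].
#' @param seed_offset Added to the derived per-model seeds; use
#'   different offsets for validation vs test predictions of the same
#'   model bank.
#' @return A named list of m `pred_set` objects (`model_1..model_m`).
#' @export
generate_base_predictions <- function(truth, cfg, seed_offset = 0) {
  stopifnot(inherits(truth, "label_set"), inherits(cfg, "synthetic_config"))
  K <- length(ls_class_names(truth))
  n <- nrow(truth)
  y <- truth$label # 0-based
  onehot <- matrix(0, n, K)
  onehot[cbind(seq_len(n), y + 1L)] <- 1
  out <- purrr::map(seq_len(cfg$m_models), function(j) {
    sub_seed <- (cfg$seed + 1009L * j + as.integer(seed_offset)) %% .Machine$integer.max
    probs <- withr::with_seed(sub_seed, {
      logits <- cfg$signal[j] * onehot + matrix(rnorm(n * K), n, K)
      softmax_rows(logits / cfg$temperature[j])
    })
    df <- tibble::as_tibble(as.data.frame(probs))
    names(df) <- ls_class_names(truth)
    df <- dplyr::bind_cols(tibble::tibble(sample_id = truth$sample_id), df)
    prediction_set(df, model_id = paste0("model_", j))
  })
  names(out) <- paste0("model_", seq_len(cfg$m_models))
  out
}

# Numerically stable row-wise softmax.
softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Stratified train/test split by diagnosis, sex, and age bin
#'
#' Splits a cohort into train and test sets while preserving the joint
#' diagnosis x sex x age-bin composition. Within each stratum the
#' subjects are shuffled (seeded) and allocated proportionally, with
#' largest-remainder rounding across strata so every stratum's test
#' share is within one subject of `test_fraction * size`. Singleton
#' strata go to train, keeping the test set usable for per-class
#' metrics.
#'
#' @param cohort A `cohort_table`.
#' @param test_fraction Target test share in (0, 1); default 0.2.
#' @param seed Integer seed for the in-stratum shuffles.
#' @return An object of class `split_result`: `train_ids`, `test_ids`,
#'   and `stratum_table` (per-stratum train/test counts). [tidy()]
#'   returns the stratum table.
#' @export
stratified_split <- function(cohort, test_fraction = 0.2, seed = 1) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (nrow(cohort) == 0) abort("Empty cohort.")
  if (test_fraction <= 0 || test_fraction >= 1) {
    abort("`test_fraction` must lie strictly between 0 and 1.")
  }
  strata <- dplyr::mutate(
    tibble::as_tibble(cohort),
    age_bin = assign_age_bin(.data$age),
    stratum = paste(.data$diagnosis, .data$sex, .data$age_bin, sep = "|")
  )
  groups <- dplyr::group_split(dplyr::group_by(strata, .data$stratum))
  sizes <- purrr::map_int(groups, nrow)
  eligible <- sizes > 1
  quota <- ifelse(eligible, test_fraction * sizes, 0)
  base <- floor(quota)
  remainder <- quota - base
  extra_total <- round(sum(quota)) - sum(base)
  n_test <- base
  if (extra_total > 0) {
    take <- order(remainder, decreasing = TRUE)[seq_len(extra_total)]
    n_test[take] <- n_test[take] + 1
  }
  n_test <- pmin(n_test, sizes - 1) # never empty a stratum's train side

  split_rows <- withr::with_seed(as.integer(seed), {
    purrr::map2(groups, n_test, function(g, k) {
      ord <- sample.int(nrow(g))
      test_pos <- ord[seq_len(k)]
      list(test = g$subject_id[test_pos],
           train = g$subject_id[setdiff(ord, test_pos)])
    })
  })
  test_ids <- sort(unlist(purrr::map(split_rows, "test")))
  train_ids <- sort(unlist(purrr::map(split_rows, "train")))

  stratum_table <- tibble::tibble(
    stratum = purrr::map_chr(groups, ~ .x$stratum[1]),
    diagnosis = purrr::map_chr(groups, ~ .x$diagnosis[1]),
    sex = purrr::map_chr(groups, ~ .x$sex[1]),
    age_bin = purrr::map_int(groups, ~ as.integer(.x$age_bin[1])),
    n = sizes,
    n_test = as.integer(n_test),
    n_train = sizes - as.integer(n_test)
  )
  structure(
    list(train_ids = train_ids, test_ids = test_ids,
         stratum_table = stratum_table,
         test_fraction = test_fraction, seed = as.integer(seed)),
    class = "split_result"
  )
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("Stratified split: %d train / %d test (target test fraction %.2f)\n",
              length(x$train_ids), length(x$test_ids), x$test_fraction))
  invisible(x)
}

#' @rdname stratified_split
#' @param x A `split_result`.
#' @param ... Unused.
#' @export
tidy.split_result <- function(x, ...) x$stratum_table
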