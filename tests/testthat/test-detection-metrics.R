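cls3 <- c("CN", "MCI", "AD")
lab <- function(v, ids = paste0("s", seq_along(v)), cn = cls3) {
  label_set(ids, v, cn)
}

test_that("confusion matrices count exactly and require aligned ids", {
  y <- lab(c(0, 0, 1, 2))
  yhat <- lab(c(0, 1, 1, 2))
  cm <- confusion_matrix(y, yhat)
  expect_equal(sum(cm), 4)
  expect_equal(unclass(cm)["CN", "MCI"], 1L, ignore_attr = TRUE)
  expect_equal(unname(diag(unclass(cm))), c(1L, 1L, 1L))

  same <- confusion_matrix(y, y)
  expect_true(all(unclass(same)[upper.tri(same) | lower.tri(same)] == 0))

  other <- lab(c(0, 1), ids = c("x1", "x2"))
  expect_error(confusion_matrix(y, other), "not aligned")
})

test_that("balanced accuracy is the unweighted mean of per-class recall", {
  y <- lab(c(0, 0, 1, 2))
  expect_equal(balanced_accuracy(confusion_matrix(y, lab(c(0, 1, 1, 2)))),
               (0.5 + 1 + 1) / 3)
  expect_equal(balanced_accuracy(confusion_matrix(y, y)), 1.0)
  # constant predictor on a 3-class set scores exactly 1/K
  expect_equal(balanced_accuracy(confusion_matrix(y, lab(c(0, 0, 0, 0)))),
               1 / 3)
  # a true class with no samples is an error, not a silent 0
  cm <- matrix(c(2, 0, 1, 1, 0, 0, 0, 0, 0), 3, byrow = TRUE)
  expect_error(balanced_accuracy(cm), "undefined")
})

test_that("weighted one-vs-rest metrics match hand-worked values", {
  y <- lab(c(0, 0, 1, 2))
  yhat <- lab(c(0, 1, 1, 2))
  m <- weighted_ovr_metrics(confusion_matrix(y, yhat))
  expect_equal(m$weighted$precision, 0.875)
  expect_equal(m$weighted$recall, 0.75)
  expect_equal(m$weighted$specificity, 11 / 12, tolerance = 1e-12)
  expect_equal(m$weighted$f1, 0.75)

  perfect <- weighted_ovr_metrics(confusion_matrix(y, y))
  expect_equal(unlist(perfect$weighted), c(precision = 1, recall = 1,
                                           specificity = 1, f1 = 1))

  # never-predicted class: precision cell scores 0 with a warning
  expect_warning(z <- weighted_ovr_metrics(confusion_matrix(y, lab(c(0, 0, 0, 0)))),
                 "Zero-division")
  expect_true(any(tidy(z)$zero_division))
})

test_that("metrics agree with brute-force oracles on every labeling of a 4-sample toy", {
  y <- c(0L, 1L, 2L, 0L)
  truth <- lab(y)
  grid <- expand.grid(a = 0:2, b = 0:2, c = 0:2, d = 0:2)
  for (i in seq_len(nrow(grid))) {
    yhat <- as.integer(grid[i, ])
    cm <- confusion_matrix(truth, lab(yhat))
    expect_equal(balanced_accuracy(cm), oracle_bacc(y, yhat, 3),
                 tolerance = 1e-12)
    got <- suppressWarnings(weighted_ovr_metrics(cm))$weighted
    want <- oracle_ovr(y, yhat, 3)
    expect_equal(as.list(got), want, tolerance = 1e-12)
  }
})

test_that("weighted recall equals plain accuracy; balanced accuracy is permutation-invariant", {
  withr::local_seed(5)
  for (i in 1:50) {
    n <- sample(6:30, 1)
    y <- c(0:2, sample(0:2, n - 3, replace = TRUE))
    yhat <- sample(0:2, n, replace = TRUE)
    cm <- confusion_matrix(lab(y), lab(yhat))
    m <- suppressWarnings(weighted_ovr_metrics(cm))
    expect_equal(m$weighted$recall, mean(y == yhat), tolerance = 1e-12)

    # consistent relabeling of classes leaves balanced accuracy unchanged
    perm <- sample(0:2)
    cm2 <- confusion_matrix(lab(perm[y + 1]), lab(perm[yhat + 1]))
    expect_equal(balanced_accuracy(cm), balanced_accuracy(cm2),
                 tolerance = 1e-12)
  }
  # equal supports: weighted recall == balanced accuracy
  y <- rep(0:2, each = 4)
  yhat <- sample(0:2, 12, replace = TRUE)
  cm <- confusion_matrix(lab(y), lab(yhat))
  expect_equal(suppressWarnings(weighted_ovr_metrics(cm))$weighted$recall,
               balanced_accuracy(cm), tolerance = 1e-12)
})

test_that("one-vs-one ROC AUC averages both directed pair AUCs", {
  # probabilities perfectly ordered by true class
  probs <- rbind(c(0.8, 0.1, 0.1), c(0.7, 0.2, 0.1),
                 c(0.2, 0.6, 0.2), c(0.1, 0.7, 0.2),
                 c(0.1, 0.2, 0.7), c(0.2, 0.2, 0.6))
  ps <- toy_pred_set(probs, cls3)
  y <- lab(c(0, 0, 1, 1, 2, 2), ids = ps$sample_id)
  expect_equal(roc_auc_ovo(ps, y), 1.0)

  # 6-sample toy vs O(n^2) rank-sum oracle
  withr::local_seed(21)
  for (i in 1:20) {
    inst <- rand_instance_full(6, 3)
    expect_equal(roc_auc_ovo(inst$ps, inst$truth),
                 oracle_auc_ovo(ps_probs(inst$ps), inst$truth$label),
                 tolerance = 1e-12)
  }
})

test_that("binary OvO reduction matches the standard AUC (pROC cross-check)", {
  skip_if_not_installed("pROC")
  withr::local_seed(13)
  for (i in 1:10) {
    n <- 30
    inst <- rand_instance_full(n, 2, class_names = c("neg", "pos"))
    got <- roc_auc_ovo(inst$ps, inst$truth)
    ref <- as.numeric(pROC::auc(
      pROC::roc(inst$truth$label, ps_probs(inst$ps)[, 2],
                levels = c(0, 1), direction = "<", quiet = TRUE)))
    expect_equal(got, ref, tolerance = 1e-12)
  }
})

test_that("OvO AUC is invariant under monotone column transforms and ~0.5 at chance", {
  withr::local_seed(17)
  # strictly monotone transform of each column (ranking is all that
  # matters): for K = 2, warp the first column with x^3 scaled back into
  # [0, 1] and complement the second, which transforms both columns
  # monotonically while keeping rows normalized
  inst2 <- rand_instance_full(40, 2, class_names = c("neg", "pos"))
  base2 <- roc_auc_ovo(inst2$ps, inst2$truth)
  p1 <- ps_probs(inst2$ps)[, 1]^3
  warped <- toy_pred_set(cbind(p1, 1 - p1), c("neg", "pos"))
  warped$sample_id <- inst2$ps$sample_id
  expect_equal(roc_auc_ovo(warped, inst2$truth), base2, tolerance = 1e-12)

  # label-free random scores average to 0.5
  aucs <- replicate(200, {
    inst <- rand_instance_full(15, 3)
    roc_auc_ovo(inst$ps, inst$truth)
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("aggregated ROC curves interpolate onto a common grid with a 95% band", {
  # identical curves -> zero-width band
  cv <- roc_points(c(0.9, 0.8, 0.4, 0.3), c(TRUE, TRUE, FALSE, FALSE))
  agg <- aggregate_roc(rep(list(cv), 300))
  expect_equal(agg$n_curves, 300)
  g <- tidy(agg)
  expect_equal(g$ci_low, g$mean_tpr, tolerance = 1e-12)
  expect_equal(g$ci_high, g$mean_tpr, tolerance = 1e-12)
  expect_equal(range(g$fpr), c(0, 1))
  expect_true(all(diff(g$mean_tpr) >= -1e-12))

  # TPR(f)=f averaged with TPR(f)=1 gives (f+1)/2 pointwise
  c1 <- tibble::tibble(fpr = c(0, 1), tpr = c(0, 1))
  c2 <- tibble::tibble(fpr = c(0, 1), tpr = c(1, 1))
  g2 <- tidy(aggregate_roc(list(c1, c2)))
  expect_equal(g2$mean_tpr, (g2$fpr + 1) / 2, tolerance = 1e-12)

  # degenerate single-point curve falls back to the (0,0)-(1,1) anchors
  g3 <- tidy(aggregate_roc(list(tibble::tibble(fpr = 0.5, tpr = 0.5))))
  expect_equal(g3$mean_tpr, g3$fpr, tolerance = 1e-12)
})
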