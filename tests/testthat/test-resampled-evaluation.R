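cls3 <- c("CN", "MCI", "AD")
lab <- function(v, ids = paste0("s", seq_along(v))) label_set(ids, v, cls3)

test_that("a constant predictor bootstraps to balanced accuracy 1/3 with a collapsed CI", {
  y <- lab(c(rep(0L, 10), rep(1L, 6), rep(2L, 4)))
  constant <- lab(rep(0L, 20), ids = y$sample_id)
  bs <- bootstrap_metric(constant, y, metric = "bacc", R = 100, seed = 4)
  expect_equal(bs$mean, 1 / 3, tolerance = 1e-12)
  expect_equal(c(bs$ci_low, bs$ci_high), c(1 / 3, 1 / 3), tolerance = 1e-12)
  expect_true(all(bs$replicates == bs$replicates[1]))
})

test_that("a trivially constant metric collapses to mean 1, CI [1, 1]", {
  y <- lab(c(0L, 1L, 2L, 0L, 1L))
  bs <- bootstrap_metric(NULL, y, metric = function(x, truth) 1,
                         R = 25, seed = 2, metric_name = "unit")
  expect_equal(bs$mean, 1)
  expect_equal(c(bs$ci_low, bs$ci_high), c(1, 1))
  expect_equal(bs$R, 25)
})

test_that("replicate values replay an independently seeded index oracle", {
  y <- lab(c(0L, 1L, 2L, 0L, 1L))
  yhat <- lab(c(0L, 1L, 1L, 0L, 2L), ids = y$sample_id)
  seed <- 77
  bs <- bootstrap_metric(yhat, y, metric = "bacc", R = 10, seed = seed)

  # oracle: replay the same seeded draw-and-redraw protocol by hand
  oracle_vals <- withr::with_seed(seed, {
    vapply(1:10, function(r) {
      repeat {
        i <- sample.int(5, 5, replace = TRUE)
        if (length(unique(y$label[i])) == 3) break
      }
      oracle_bacc(y$label[i], yhat$label[i], 3)
    }, numeric(1))
  })
  expect_equal(bs$replicates, oracle_vals, tolerance = 1e-12)
})

test_that("fixed seeds make bootstrap summaries bit-identical, and shared indices align strategies", {
  withr::local_seed(41)
  inst <- rand_instance_full(40, 3)
  a <- bootstrap_metric(inst$ps, inst$truth, metric = "bacc", R = 50, seed = 9)
  b <- bootstrap_metric(inst$ps, inst$truth, metric = "bacc", R = 50, seed = 9)
  expect_identical(a$replicates, b$replicates)
  expect_identical(glance(a), glance(b))

  # two identical prediction sets under shared indices: identical summaries
  idx <- bootstrap_indices(inst$truth, R = 50, seed = 10)
  s1 <- bootstrap_metric(inst$ps, inst$truth, metric = "ece", indices = idx)
  s2 <- bootstrap_metric(inst$ps, inst$truth, metric = "ece", indices = idx)
  expect_identical(s1$replicates, s2$replicates)
})

test_that("bootstrap CI width shrinks with test-set size for a sample-mean metric", {
  withr::local_seed(43)
  width <- vapply(c(50, 200, 800), function(n) {
    y <- lab(sample(0:2, n, replace = TRUE), ids = sprintf("t%04d", 1:n))
    bs <- bootstrap_metric(NULL, y,
                           metric = function(x, truth) mean(truth$label == 0),
                           R = 100, seed = n, metric_name = "p0")
    bs$ci_high - bs$ci_low
  }, numeric(1))
  expect_true(all(diff(width) < 0))
})

test_that("z comparison follows the two-sample formula with star coding", {
  mk <- function(vals, name = "bacc") {
    structure(list(metric_name = name, replicates = vals, mean = mean(vals),
                   ci_low = unname(quantile(vals, 0.025)),
                   ci_high = unname(quantile(vals, 0.975)),
                   R = length(vals), seed = 1L),
              class = "bootstrap_summary")
  }
  withr::local_seed(47)
  a <- mk(rnorm(100, 0.5, 0.02))
  same <- z_compare(a, a)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  expect_equal(same$code, "ns")

  # arithmetic oracle: means 0.50 vs 0.60, sd 0.02, R = 100 -> z = -35.36
  va <- scale(rnorm(100)) * 0.02 + 0.50 # exact mean/sd
  vb <- scale(rnorm(100)) * 0.02 + 0.60
  zc <- z_compare(mk(as.numeric(va)), mk(as.numeric(vb)))
  expect_equal(zc$z, -0.1 / sqrt(2 * 0.02^2 / 100), tolerance = 1e-9)
  expect_equal(round(zc$z, 2), -35.36)
  expect_lt(zc$p, 0.001)
  expect_equal(zc$code, "***")

  # antisymmetry
  b <- mk(rnorm(100, 0.55, 0.03))
  expect_equal(z_compare(a, b)$z, -z_compare(b, a)$z, tolerance = 1e-12)

  # degenerate zero-variance cases
  expect_equal(z_compare(mk(rep(0.4, 10)), mk(rep(0.4, 10)))$p, 1)
  expect_warning(deg <- z_compare(mk(rep(0.4, 10)), mk(rep(0.5, 10))),
                 "Degenerate")
  expect_equal(deg$p, 0)
  expect_error(z_compare(a, mk(rnorm(10), name = "ece")), "mismatch")
})

test_that("chi-square contingency test matches margins and hand computations", {
  # table proportional to its margins -> no association
  prop <- outer(c(10, 20), c(3, 7)) / 10
  expect_equal(pearson_chi_square(prop * 10)$chi2, 0, tolerance = 1e-12)

  res <- pearson_chi_square(rbind(c(132, 229), c(122, 100), c(41, 27)))
  expect_equal(res$dof, 2)
  expect_equal(res$chi2, 25.64, tolerance = 0.01)
  expect_lt(res$p, 0.001)

  toy <- pearson_chi_square(rbind(c(10, 0), c(0, 10)))
  expect_equal(toy$chi2, 20)
  expect_equal(toy$dof, 1)

  expect_error(pearson_chi_square(rbind(c(1, 0), c(2, 0))), "margin")
  expect_error(pearson_chi_square(matrix(1:3, 1)), "2 x 2")
})

test_that("comparison tables mark the reference and star the rest", {
  mk <- function(vals, name) {
    structure(list(metric_name = name, replicates = vals, mean = mean(vals),
                   ci_low = unname(quantile(vals, 0.025)),
                   ci_high = unname(quantile(vals, 0.975)),
                   R = length(vals), seed = 1L),
              class = "bootstrap_summary")
  }
  withr::local_seed(53)
  # two identical models -> ref plus ns
  v <- rnorm(100, 0.6, 0.02)
  tab <- comparison_table(list(m1 = mk(v, "bacc"), m2 = mk(v, "bacc")))
  expect_setequal(tab$code, c("ref", "ns"))

  # for calibration error the reference is the MINIMUM mean
  es <- list(a = mk(rnorm(100, 0.20, 0.01), "ece"),
             b = mk(rnorm(100, 0.16, 0.01), "ece"),
             c = mk(rnorm(100, 0.25, 0.01), "ece"))
  etab <- comparison_table(es, minimize = TRUE)
  expect_equal(etab$model[etab$code == "ref"], "b")

  # stars agree with direct z_compare of each row against the reference
  for (mdl in c("a", "c")) {
    expect_equal(etab$code[etab$model == mdl],
                 z_compare(es[[mdl]], es$b)$code)
  }

  # average-of-means row for base-model groups
  atab <- comparison_table(es, minimize = TRUE, average_of_means = TRUE)
  avg <- atab[atab$model == "Average of means", ]
  expect_equal(avg$mean, mean(vapply(es, `[[`, numeric(1), "mean")))

  # single-member group is emitted with ref only
  solo <- comparison_table(list(only = mk(v, "bacc")))
  expect_equal(solo$code, "ref")
})
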