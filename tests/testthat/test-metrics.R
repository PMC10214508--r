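test_that("confusion counts follow the score >= threshold convention", {
  cm <- confusion(c(1, 1, 0, 0), c(0.9, 0.2, 0.8, 0.1))
  expect_equal(unlist(cm), c(TP = 1L, FN = 1L, FP = 1L, TN = 1L))
  perfect <- confusion(c(1, 0), c(0.9, 0.1))
  expect_equal(perfect$FN + perfect$FP, 0L)
  # boundary scores count as positive
  tied <- confusion(c(1, 0), c(0.5, 0.5), threshold = 0.5)
  expect_equal(unlist(tied), c(TP = 1L, FN = 0L, FP = 1L, TN = 0L))
  expect_error(confusion(c(1, 0), 0.5), "length")
})

test_that("metric_vector matches hand-computed values and conventions", {
  mv <- metric_vector(tibble::tibble(TP = 30, FN = 5, FP = 10, TN = 30))
  expect_equal(mv$accuracy, 0.8)
  expect_equal(mv$precision, 0.75)
  expect_equal(mv$sensitivity, 30 / 35)
  expect_equal(mv$specificity, 0.75)
  expect_equal(mv$f1, 0.8)
  expect_equal(mv$mcc, (30 * 30 - 10 * 5) / sqrt(40 * 35 * 40 * 35))
  expect_equal(mv$mcc, 0.607, tolerance = 1e-3)

  perfect <- metric_vector(tibble::tibble(TP = 5, FN = 0, FP = 0, TN = 5))
  expect_equal(unname(unlist(perfect)), rep(1, 6))

  # all-positive predictions on balanced labels: MCC 0 by convention;
  # specificity is 0/(0+5) = 0 (defined); with no negative predictions at
  # all (TN = FN = 0 and FP = 0) precision of the negative side would be
  # the undefined one, which cannot occur here
  allpos <- metric_vector(tibble::tibble(TP = 5, FN = 0, FP = 5, TN = 0))
  expect_equal(allpos$mcc, 0)
  expect_equal(allpos$specificity, 0)
  # a truly undefined denominator: no positive predictions -> precision NA
  allneg <- metric_vector(tibble::tibble(TP = 0, FN = 5, FP = 0, TN = 5))
  expect_true(is.na(allneg$precision))
  expect_equal(allneg$mcc, 0)
})

test_that("MCC is antisymmetric under label flip", {
  withr::with_seed(5, {
    for (rep in 1:20) {
      y <- c(0, 1, rbinom(10, 1, 0.5))
      s <- runif(12)
      m1 <- metric_vector(confusion(y, s))$mcc
      m2 <- metric_vector(confusion(1 - y, s))$mcc
      expect_equal(m1, -m2)
    }
  })
})

test_that("accuracy decomposes into prevalence-weighted sensitivity and specificity", {
  withr::with_seed(8, {
    for (rep in 1:20) {
      y <- c(0, 1, rbinom(15, 1, 0.4))
      s <- runif(17)
      mv <- metric_vector(confusion(y, s))
      prev <- mean(y)
      expect_equal(mv$accuracy, prev * mv$sensitivity + (1 - prev) * mv$specificity)
    }
  })
})

test_that("ROC AUC equals brute-force pair counting and handles fixed cases", {
  expect_equal(roc_curve_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.3, 0.2))$auc, 1.0)
  expect_equal(roc_curve_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.3, 0.2))$auc, 0.75)
  expect_equal(roc_curve_auc(c(1, 1, 0, 0), c(0.1, 0.2, 0.8, 0.9))$auc, 0.0)
  expect_error(roc_curve_auc(c(1, 1), c(0.5, 0.6)), "class")

  withr::with_seed(13, {
    for (rep in 1:200) {
      n <- sample(4:30, 1)
      y <- c(0, 1, rbinom(n - 2, 1, runif(1, 0.2, 0.8)))
      s <- round(runif(n), sample(1:3, 1))  # coarse rounding provokes ties
      expect_equal(roc_curve_auc(y, s)$auc, oracle_roc_auc(y, s))
    }
  })
})

test_that("ROC AUC agrees with pROC on random inputs", {
  skip_if_not_installed("pROC")
  withr::with_seed(29, {
    for (rep in 1:25) {
      y <- c(0, 1, rbinom(20, 1, 0.5))
      s <- runif(22)
      ours <- roc_curve_auc(y, s)$auc
      ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<")))
      expect_equal(ours, ref)
    }
  })
})

test_that("PR AUC matches its oracle sweep and closed forms", {
  expect_equal(pr_curve_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.3, 0.2))$auc, 1.0)
  # constant scores: single-point curve, AUC = prevalence
  expect_equal(pr_curve_auc(c(1, 0, 0, 1, 0), rep(0.4, 5))$auc, 0.4)
  expect_error(pr_curve_auc(c(0, 0), c(0.1, 0.2)), "positive")

  withr::with_seed(17, {
    for (rep in 1:50) {
      n <- sample(5:20, 1)
      y <- c(1, rbinom(n - 1, 1, 0.5))
      s <- round(runif(n), 2)
      expect_equal(pr_curve_auc(y, s)$auc, oracle_pr_auc(y, s))
    }
  })
})

test_that("curves respect their monotonicity invariants", {
  withr::with_seed(23, {
    for (rep in 1:20) {
      y <- c(0, 1, rbinom(15, 1, 0.5))
      s <- round(runif(17), 2)
      roc <- roc_curve_auc(y, s)$curve
      expect_true(all(diff(roc$fpr) >= 0))
      expect_true(all(diff(roc$tpr) >= 0))
      expect_equal(c(roc$fpr[1], roc$tpr[1]), c(0, 0))
      expect_equal(c(dplyr::last(roc$fpr), dplyr::last(roc$tpr)), c(1, 1))
      pr <- pr_curve_auc(y, s)$curve
      expect_equal(range(pr$recall), c(0, 1))
    }
  })
})

test_that("aggregation uses sample sd and excludes undefined values with a count", {
  rows <- tibble::tibble(accuracy = c(0.8, 1.0), mcc = c(0.5, 0.5))
  agg <- aggregate_metrics(rows)
  expect_equal(agg$mean[agg$metric == "accuracy"], 0.9)
  expect_equal(agg$sd[agg$metric == "accuracy"], sqrt(0.02), tolerance = 1e-10)
  expect_equal(agg$sd[agg$metric == "mcc"], 0)

  rows2 <- tibble::tibble(specificity = c(0.8, NA, 1.0))
  agg2 <- aggregate_metrics(rows2)
  expect_equal(agg2$mean, 0.9)
  expect_equal(agg2$n_undefined, 1L)
  expect_error(aggregate_metrics(rows[1, ]), "two")
})

test_that("pooled RSD averages per-metric relative dispersion", {
  s <- tibble::tibble(metric = c("a", "b"), mean = c(0.5, 1.0), sd = c(0.05, 0.05))
  expect_equal(pooled_rsd(s), 7.5)
  s0 <- tibble::tibble(metric = "a", mean = 0.8, sd = 0)
  expect_equal(pooled_rsd(s0), 0)
  szero <- tibble::tibble(metric = c("a", "b"), mean = c(0, 0.5), sd = c(1, 0.1))
  expect_equal(pooled_rsd(szero), 20)  # zero-mean metric skipped
})
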