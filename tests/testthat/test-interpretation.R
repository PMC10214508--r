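# a fixed trained model on a small synthetic problem, shared across tests
shap_fixture <- local({
  ds <- generate_dataset(synthetic_spec(40, 6, 2, effect_fold = 4, seed = 71))
  x <- as.matrix(ds$table[, -(1:2)])
  y <- ds$table$label
  list(model = fit_model(model_spec("XGB", nrounds = 30), x, y),
       x = x, y = y)
})

test_that("exact attributions satisfy local accuracy and the null-player axiom", {
  f <- shap_fixture
  bg <- f$x[1:20, ]
  inst <- f$x[21:26, ]
  phi <- shapley_attributions(f$model, bg, inst, method = "exact")
  total <- attr(phi, "base_value") + rowSums(phi)
  expect_equal(total, unname(predict_scores(f$model, inst)), tolerance = 1e-6)

  # constant model: a ridge-logistic fit on pure noise with a huge penalty
  const <- fit_model(model_spec("LR", lambda = 1e8), f$x, f$y)
  spread <- diff(range(predict_scores(const, f$x)))
  expect_lt(spread, 1e-6)
  phi0 <- shapley_attributions(const, bg, inst, method = "exact")
  expect_lt(max(abs(phi0)), 1e-8)
})

test_that("exact attributions match brute-force Shapley enumeration", {
  f <- shap_fixture
  bg <- f$x[1:15, ]
  x0 <- f$x[30, , drop = FALSE]
  phi <- shapley_attributions(f$model, bg, x0, method = "exact")
  p <- ncol(bg)
  v <- function(S) {
    z <- bg
    for (j in S) z[, j] <- x0[1, j]
    mean(predict_scores(f$model, z))
  }
  expect_equal(as.numeric(phi), oracle_shapley(p, v), tolerance = 1e-8)
})

test_that("the linear closed form w_i (x_i - E[x_i]) is recovered", {
  # linear score model built directly on the mlp machinery: one linear layer
  w <- c(2, 0)
  lin <- structure(list(
    spec = model_spec("NN"), p = 2L,
    prep = list(median = c(0, 0), center = c(0, 0), scale = c(1, 1)),
    fit = structure(list(layers = list(list(W = matrix(w, 2, 1), b = 0)),
                         activation = "relu", p = 2L), class = "mzclass_mlp"),
    extra = NULL), class = "trained_model")
  withr::with_seed(5, {
    bg <- cbind(rnorm(200), rnorm(200))
  })
  inst <- rbind(c(1, 5))
  phi <- shapley_attributions(lin, bg, inst, method = "exact")
  mu <- colMeans(bg)
  # on the logit scale the model is linear; scores pass through a sigmoid,
  # so compare against the enumeration of the sigmoid model itself
  v <- function(S) {
    z <- bg
    for (j in S) z[, j] <- inst[1, j]
    mean(plogis(z %*% w))
  }
  expect_equal(as.numeric(phi), oracle_shapley(2, v), tolerance = 1e-10)
  # feature 2 has zero weight: exactly zero attribution
  expect_equal(phi[1, 2], 0)
  # feature 1 attribution has the sign and rough size of w1 (x1 - mu1)
  expect_gt(phi[1, 1], 0)
})

test_that("sampled attributions converge to the exact oracle as budget grows", {
  f <- shap_fixture
  bg <- f$x[1:20, ]
  inst <- f$x[31:34, ]
  exact <- shapley_attributions(f$model, bg, inst, method = "exact")
  rmse <- function(budget, seed) {
    est <- shapley_attributions(f$model, bg, inst, budget = budget,
                                seed = seed, method = "sampling")
    sqrt(mean((est - exact)^2))
  }
  lo <- rmse(7 * 4, 1)       # 4 walks
  hi <- rmse(7 * 256, 1)     # 256 walks
  expect_lt(hi, lo)
  expect_lt(hi, 0.02)
  # seeded: identical under the same seed
  expect_identical(
    shapley_attributions(f$model, bg, inst, budget = 70, seed = 9, method = "sampling"),
    shapley_attributions(f$model, bg, inst, budget = 70, seed = 9, method = "sampling")
  )
  expect_error(shapley_attributions(f$model, bg[0, ], inst), "background")
})

test_that("functionally identical features get equal exact attributions", {
  # duplicated informative column, model forced to treat them symmetrically
  withr::with_seed(81, {
    z <- rnorm(60)
    y <- as.integer(z + rnorm(60, sd = 0.4) > 0)
    x <- cbind(a = z, b = z)
  })
  m <- fit_model(model_spec("LR", lambda = 0.1), x, y)
  phi <- shapley_attributions(m, x, x[1:8, ], method = "exact")
  # the ridge fit itself is symmetric only to coordinate-descent precision
  expect_equal(phi[, "a"], phi[, "b"], tolerance = 1e-4)
})

test_that("absolute-average aggregation reduces attribution matrices as specified", {
  m1 <- matrix(c(1, -3, -1, 1), 2, 2,
               dimnames = list(NULL, c("f1", "f2")))
  expect_equal(aggregate_shap(m1), c(f1 = 2, f2 = 1))
  expect_equal(aggregate_shap(list(m1, m1)), c(f1 = 2, f2 = 1))  # idempotent mean
  expect_equal(aggregate_shap(m1 * 0), c(f1 = 0, f2 = 0))
  # the alternative reading cancels opposing effects
  expect_equal(aggregate_shap(m1, mode = "abs_mean"), c(f1 = 1, f2 = 0))
  m_bad <- matrix(0, 2, 2, dimnames = list(NULL, c("g1", "g2")))
  expect_error(aggregate_shap(list(m1, m_bad)), "feature sets")
})

test_that("regulation direction follows the abundance-label correlation", {
  tbl <- tibble::tibble(
    subject_id = sprintf("s%d", 1:6),
    label = c(1L, 1L, 1L, 0L, 0L, 0L),
    up_feature = c(9, 8, 10, 2, 1, 3),
    anti = 1 - c(1, 1, 1, 0, 0, 0),
    const = rep(4, 6)
  )
  d <- regulation_direction(tbl)
  expect_equal(d$direction[d$feature_id == "up_feature"], "up")
  expect_equal(d$direction[d$feature_id == "anti"], "down")
  expect_equal(d$direction[d$feature_id == "const"], "none")
})

test_that("feature ranking sorts by score with stable index tie-breaks", {
  scores <- c(f1 = 0.5, f2 = 2.0, f3 = 1.0)
  rk <- rank_features(scores, top_k = 2)
  expect_equal(rk$feature_id, c("f2", "f3", "f1"))
  expect_equal(rk$rank, 1:3)
  expect_equal(rk$top, c(TRUE, TRUE, FALSE))

  all_of_them <- rank_features(scores, top_k = 10)
  expect_true(all(all_of_them$top))

  tied <- rank_features(c(a = 1, b = 1, c = 2), top_k = 1)
  expect_equal(tied$feature_id, c("c", "a", "b"))  # lower index first among ties
})
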