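#' Resampling plan for repeated 60/40 train/test evaluation
#'
#' The evaluation protocol is Monte-Carlo cross-validation: the cohort is
#' split at random `n_iterations` times into a training fraction (default
#' 60%, size `floor(train_fraction * n)`, sampled without replacement) and a
#' test remainder (40%). Splits are not stratified by default; a degenerate
#' single-class test fold simply leaves that iteration's class-conditional
#' metrics undefined.
#'
#' @param n_iterations Number of random splits (default 100).
#' @param train_fraction Fraction of subjects in the training fold, in (0, 1).
#' @param stratified Preserve class proportions per fold (within rounding)?
#' @param seed Integer seed; the whole split sequence is reproducible from it.
#' @return An object of class `bootstrap_plan`.
#' @export
bootstrap_plan <- function(n_iterations = 100L, train_fraction = 0.6,
                           stratified = FALSE, seed = 1L) {
  if (n_iterations < 1) abort("n_iterations must be positive")
  if (train_fraction <= 0 || train_fraction >= 1) abort("train_fraction must be in (0, 1)")
  structure(
    list(n_iterations = as.integer(n_iterations), train_fraction = train_fraction,
         stratified = isTRUE(stratified), seed = as.integer(seed)),
    class = "bootstrap_plan"
  )
}

#' Generate the train/test splits of a plan
#'
#' @param n Number of subjects (>= 5).
#' @param plan A [bootstrap_plan()].
#' @param labels Binary labels, required when `plan$stratified` is `TRUE`.
#' @return A list of `plan$n_iterations` lists, each with integer vectors
#'   `train` and `test` that are disjoint and together cover `1:n`.
#' @export
make_splits <- function(n, plan, labels = NULL) {
  stopifnot(inherits(plan, "bootstrap_plan"))
  if (n < 5) abort("need at least 5 subjects to split")
  n_train <- floor(plan$train_fraction * n)
  if (n_train < 2 || n - n_train < 2) abort("train and test folds must each hold >= 2 subjects")
  if (plan$stratified && is.null(labels)) abort("stratified splits need labels")
  with_seed(plan$seed, {
    purrr::map(seq_len(plan$n_iterations), function(i) {
      if (plan$stratified) {
        idx1 <- which(labels == 1L); idx0 <- which(labels == 0L)
        k1 <- round(plan$train_fraction * length(idx1))
        k1 <- max(1L, min(length(idx1) - 1L, k1))
        k0 <- n_train - k1
        k0 <- max(1L, min(length(idx0) - 1L, k0))
        train <- sort(c(sample(idx1, k1), sample(idx0, k0)))
      } else {
        train <- sort(sample.int(n, n_train))
      }
      list(train = train, test = setdiff(seq_len(n), train))
    })
  })
}

#' Evaluate one classifier under the resampling plan
#'
#' For each split the preprocessing and the model are fitted on the training
#' fold only, the test fold is scored, and the confusion matrix, the six
#' classification metrics and both AUCs are recorded. The whole feature table
#' goes in — no feature preselection. Optionally, per-iteration Shapley
#' attributions of the test fold are computed with the training fold as
#' background.
#'
#' @param data Feature-table tibble including the label column.
#' @param spec A [model_spec()].
#' @param plan A [bootstrap_plan()].
#' @param label Name of the label column.
#' @param attributions Compute per-iteration test-fold Shapley attributions?
#' @param shap_budget Coalition evaluations per explained subject (see
#'   [shapley_attributions()]).
#' @return An object of class `bootstrap_result`: list with `metrics` (tibble,
#'   one row per iteration), `confusions`, `splits`, `summary`
#'   ([aggregate_metrics()] output), `pooled` (tibble of pooled out-of-fold
#'   predictions: `iteration`, `subject`, `label`, `score`), `attributions`
#'   (list of matrices or `NULL`), `spec`, `plan`.
#' @export
run_evaluation <- function(data, spec, plan = bootstrap_plan(), label = "label",
                           attributions = FALSE, shap_budget = 128L) {
  validate_feature_table(data, label = label)
  if (!label %in% names(data)) abort("data has no label column")
  y <- data[[label]]
  assert_binary_labels(y)
  x <- ft_matrix(data, label = label)
  splits <- make_splits(nrow(x), plan, labels = y)

  rows <- vector("list", length(splits))
  cms <- vector("list", length(splits))
  pooled <- vector("list", length(splits))
  attr_mats <- if (attributions) vector("list", length(splits)) else NULL

  for (i in seq_along(splits)) {
    sp <- splits[[i]]
    spec_i <- spec
    spec_i$seed <- child_seed(plan$seed, i * 2L + spec$seed)
    if (min(table(factor(y[sp$train], levels = c(0, 1)))) < 2) {
      # degenerate training fold: cannot fit; the iteration stays undefined
      warn(paste0("iteration ", i, ": training fold has fewer than 2 subjects",
                  " in one class; metrics undefined"))
      na6 <- tibble(accuracy = NA_real_, precision = NA_real_,
                    sensitivity = NA_real_, specificity = NA_real_,
                    f1 = NA_real_, mcc = NA_real_)
      rows[[i]] <- dplyr::bind_cols(tibble(iteration = i), na6,
                                    tibble(auc_roc = NA_real_, auc_pr = NA_real_))
      cms[[i]] <- tibble(iteration = i, TP = NA_integer_, FN = NA_integer_,
                         FP = NA_integer_, TN = NA_integer_)
      pooled[[i]] <- tibble(iteration = i, subject = character(0),
                            label = integer(0), score = numeric(0))[0, ]
      next
    }
    model <- fit_model(spec_i, x[sp$train, , drop = FALSE], y[sp$train])
    scores <- predict_scores(model, x[sp$test, , drop = FALSE])
    y_test <- y[sp$test]

    cm <- confusion(y_test, scores)
    mv <- metric_vector(cm)
    aucs <- if (length(unique(y_test)) == 2) {
      tibble(auc_roc = roc_curve_auc(y_test, scores)$auc,
             auc_pr = pr_curve_auc(y_test, scores)$auc)
    } else {
      tibble(auc_roc = NA_real_, auc_pr = NA_real_)
    }
    rows[[i]] <- dplyr::bind_cols(tibble(iteration = i), mv, aucs)
    cms[[i]] <- dplyr::bind_cols(tibble(iteration = i), cm)
    pooled[[i]] <- tibble(iteration = i, subject = rownames(x)[sp$test],
                          label = y_test, score = scores)
    if (attributions) {
      attr_mats[[i]] <- shapley_attributions(
        model, background = x[sp$train, , drop = FALSE],
        instances = x[sp$test, , drop = FALSE],
        budget = shap_budget, seed = child_seed(plan$seed, 7919L + i)
      )
    }
  }

  metrics <- dplyr::bind_rows(rows)
  structure(
    list(
      metrics = metrics,
      confusions = dplyr::bind_rows(cms),
      splits = splits,
      summary = aggregate_metrics(dplyr::select(metrics, -"iteration")),
      pooled = dplyr::bind_rows(pooled),
      attributions = attr_mats,
      spec = spec, plan = plan
    ),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("<bootstrap_result> ", x$spec$family, ", ", x$plan$n_iterations,
      " iterations (train fraction ", x$plan$train_fraction, ")\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Grid search by mean Matthews correlation coefficient
#'
#' Evaluates every hyperparameter combination of the grid under *identical*
#' splits (the plan's seed fixes one split sequence reused for all specs) and
#' returns the spec with the highest mean MCC across iterations. Ties go to
#' the first enumerated spec.
#'
#' @inheritParams run_evaluation
#' @param grid A [hyper_grid()].
#' @return A list with `best_spec`, `best_index`, and `summaries` (tibble: one
#'   row per spec with its mean/sd MCC).
#' @export
grid_search <- function(data, grid, plan = bootstrap_plan(), label = "label") {
  specs <- enumerate_grid(grid)
  if (length(specs) == 0) abort("empty grid")
  res <- purrr::imap(specs, function(sp, i) {
    r <- run_evaluation(data, sp, plan, label = label)
    s <- dplyr::filter(r$summary, .data$metric == "mcc")
    tibble(spec_index = i, mcc_mean = s$mean, mcc_sd = s$sd)
  })
  summaries <- dplyr::bind_rows(res)
  best <- which.max(summaries$mcc_mean)  # which.max takes the first maximum
  list(best_spec = specs[[best]], best_index = best, summaries = summaries)
}

#' Label-permutation control
#'
#' Destroys the label-feature association by randomly permuting the class
#' labels, then reruns the full resampling evaluation. On any dataset the mean
#' test accuracy of a sound pipeline should then be statistically
#' indistinguishable from chance (0.5 for balanced cohorts); a systematic
#' departure signals information leakage.
#'
#' @inheritParams run_evaluation
#' @param n_permutations Number of independent permutation replicates.
#' @param seed Seed for the permutations (separate from the plan's split seed).
#' @param permutations Optional list of explicit permutation vectors of
#'   `1:nrow(data)`, overriding the random draws (e.g. the identity
#'   permutation as a control of the control).
#' @return A list of `bootstrap_result`s, one per replicate, each carrying the
#'   permuted labels used in `$permuted_labels`.
#' @export
permutation_control <- function(data, spec, plan = bootstrap_plan(),
                                n_permutations = 1L, seed = 1L,
                                label = "label", permutations = NULL) {
  if (n_permutations < 1) abort("n_permutations must be positive")
  perms <- permutations %||%
    with_seed(seed, purrr::map(seq_len(n_permutations),
                               ~ sample.int(nrow(data))))
  purrr::map(perms, function(pm) {
    d <- data
    d[[label]] <- data[[label]][pm]
    r <- run_evaluation(d, spec, plan, label = label)
    r$permuted_labels <- d[[label]]
    r
  })
}
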