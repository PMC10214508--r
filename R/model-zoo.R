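#' Classifier specifications
#'
#' A model spec names one of the six supported classifier families and its
#' hyperparameters. All families share one train/score contract: training
#' fits median imputation and per-feature standardisation on the training
#' fold only, then fits the family's learner on the preprocessed matrix;
#' scoring returns a class-1 probability-like score in [0, 1].
#'
#' Families and their hyperparameters (defaults in parentheses):
#' * `NN` — multilayer perceptron: `hidden` (c(64, 32)), `activation`
#'   ("relu"), `learning_rate` (0.01), `weight_decay` (1e-4), `epochs` (200),
#'   `batch_size` (Inf, i.e. full batch), `dropout` (0.2).
#' * `XGB` — gradient-boosted trees: `nrounds` (100), `max_depth` (3),
#'   `eta` (0.1), `subsample` (1), `colsample_bytree` (1).
#' * `RF` — random forest: `num_trees` (500), `mtry` (NULL = sqrt(p); a value
#'   below 1 is a fraction of the feature count), `min_node_size` (1).
#' * `LR` — L2-penalised (ridge) logistic regression: `lambda` (0.01).
#' * `SVM` — support vector machine: `kernel` ("radial"), `cost` (1),
#'   `gamma` (NULL = 1/p). Scores are a sigmoid of the signed margin.
#' * `LDA` — linear discriminant analysis: `prior` (NULL = empirical class
#'   frequencies; a scalar is read as the prior probability of class 1).
#'
#' @param family One of `"NN"`, `"XGB"`, `"RF"`, `"LR"`, `"SVM"`, `"LDA"`.
#' @param ... Named hyperparameters overriding the family defaults.
#' @param seed Integer seed used by stochastic learners.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family = c("NN", "XGB", "RF", "LR", "SVM", "LDA"), ...,
                       seed = 1L) {
  family <- match.arg(family)
  hp <- list(...)
  defaults <- model_defaults(family)
  unknown <- setdiff(names(hp), names(defaults))
  if (length(unknown)) {
    abort(paste0("unknown hyperparameter(s) for ", family, ": ",
                 paste(unknown, collapse = ", ")))
  }
  structure(
    list(family = family, hyperparameters = utils::modifyList(defaults, hp),
         seed = as.integer(seed)),
    class = "model_spec"
  )
}

model_defaults <- function(family) {
  switch(family,
    NN  = list(hidden = c(64L, 32L), activation = "relu", learning_rate = 0.01,
               weight_decay = 1e-4, epochs = 200L, batch_size = Inf,
               dropout = 0.2),
    XGB = list(nrounds = 100L, max_depth = 3L, eta = 0.1, subsample = 1,
               colsample_bytree = 1),
    RF  = list(num_trees = 500L, mtry = NULL, min_node_size = 1L),
    LR  = list(lambda = 0.01),
    SVM = list(kernel = "radial", cost = 1, gamma = NULL),
    LDA = list(prior = NULL)
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", x$family, " (seed ", x$seed, ")\n", sep = "")
  hp <- x$hyperparameters
  for (nm in names(hp)) {
    cat("  ", nm, " = ", paste(format(hp[[nm]]), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Hyperparameter grids
#'
#' A grid is a family plus a named list of axes, each a finite vector (or
#' list) of candidate values. [enumerate_grid()] expands the full Cartesian
#' product in a deterministic order: axes sorted by name, values in their
#' listed order, later axes varying fastest.
#'
#' @param family Classifier family (see [model_spec()]).
#' @param axes Named list of candidate-value vectors; empty means
#'   "family defaults only".
#' @param seed Seed copied into every enumerated spec.
#' @return `hyper_grid()`: an object of class `hyper_grid`;
#'   `enumerate_grid()`: a list of `model_spec`s.
#' @export
hyper_grid <- function(family, axes = list(), seed = 1L) {
  family <- match.arg(family, c("NN", "XGB", "RF", "LR", "SVM", "LDA"))
  if (length(axes)) {
    if (is.null(names(axes)) || any(names(axes) == "")) abort("all axes must be named")
    bad <- purrr::map_lgl(axes, ~ length(.x) == 0)
    if (any(bad)) abort("empty grid axis")
    unknown <- setdiff(names(axes), names(model_defaults(family)))
    if (length(unknown)) {
      abort(paste0("unknown hyperparameter axis for ", family, ": ",
                   paste(unknown, collapse = ", ")))
    }
  }
  structure(list(family = family, axes = axes, seed = as.integer(seed)),
            class = "hyper_grid")
}

#' @rdname hyper_grid
#' @param grid A `hyper_grid`.
#' @export
enumerate_grid <- function(grid) {
  stopifnot(inherits(grid, "hyper_grid"))
  axes <- grid$axes
  if (length(axes) == 0) return(list(model_spec(grid$family, seed = grid$seed)))
  axes <- axes[order(names(axes))]
  counts <- purrr::map_int(axes, length)
  idx <- expand.grid(rev(purrr::map(counts, seq_len)), KEEP.OUT.ATTRS = FALSE)
  idx <- idx[, rev(seq_along(axes)), drop = FALSE]
  names(idx) <- names(axes)
  purrr::map(seq_len(nrow(idx)), function(i) {
    hp <- purrr::imap(axes, function(vals, nm) {
      v <- vals[[idx[i, nm]]]
      v
    })
    do.call(model_spec, c(list(family = grid$family, seed = grid$seed), hp))
  })
}

#' Load a packaged default grid
#'
#' Default grids for the six families ship as JSON under
#' `inst/grids/`; this reads one into a [hyper_grid()].
#'
#' @param family Classifier family.
#' @param seed Seed for the resulting grid.
#' @return A `hyper_grid`.
#' @export
default_grid <- function(family, seed = 1L) {
  path <- system.file("grids", paste0(tolower(family), ".json"), package = "mzclass")
  if (path == "") abort(paste0("no packaged grid for family ", family))
  axes <- jsonlite::read_json(path, simplifyVector = TRUE)
  axes <- purrr::map(axes, function(a) {
    if (is.matrix(a)) purrr::map(asplit(a, 1), as.vector) else a
  })
  hyper_grid(family, axes, seed = seed)
}

#' Fit a classifier on a (possibly incomplete) feature matrix
#'
#' @param spec A [model_spec()].
#' @param x Numeric matrix, subjects in rows; `NA` entries allowed (median
#'   imputation is fitted on `x` itself).
#' @param y Binary 0/1 vector, both classes present.
#' @return An object of class `trained_model`.
#' @export
fit_model <- function(spec, x, y) {
  stopifnot(inherits(spec, "model_spec"))
  x <- as.matrix(x)
  assert_binary_labels(y)
  if (nrow(x) != length(y)) abort("x rows must match length(y)")
  prep <- fit_preprocessor(x)
  xs <- apply_preprocessor(prep, x)
  hp <- spec$hyperparameters
  fit <- switch(spec$family,
    NN = mlp_train(xs, y, hidden = hp$hidden, activation = hp$activation,
                   learning_rate = hp$learning_rate,
                   weight_decay = hp$weight_decay, epochs = hp$epochs,
                   batch_size = hp$batch_size, dropout = hp$dropout,
                   seed = spec$seed),
    XGB = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = hp$max_depth,
                    eta = hp$eta, subsample = hp$subsample,
                    colsample_bytree = hp$colsample_bytree,
                    nthread = 1, seed = spec$seed),
      data = xgboost::xgb.DMatrix(xs, label = y), nrounds = hp$nrounds,
      verbose = 0
    ),
    RF = ranger::ranger(
      x = xs, y = factor(y, levels = c(0, 1)), probability = TRUE,
      num.trees = hp$num_trees, mtry = resolve_mtry(hp$mtry, ncol(xs)),
      min.node.size = hp$min_node_size, seed = spec$seed, num.threads = 1
    ),
    LR = fit_ridge_logistic(xs, y, hp$lambda),
    SVM = fit_svm(xs, y, hp),
    LDA = suppressWarnings(MASS::lda(
      x = xs[, apply(xs, 2, stats::sd) > 0, drop = FALSE],
      grouping = factor(y, levels = c(0, 1)),
      prior = resolve_prior(hp$prior, y),
      tol = 1e-12
    ))
  )
  extra <- if (spec$family == "LDA") {
    list(lda_keep = which(apply(xs, 2, stats::sd) > 0))
  } else NULL
  structure(list(spec = spec, prep = prep, fit = fit, p = ncol(x),
                 extra = extra),
            class = "trained_model")
}

# RF mtry: NULL = sqrt(p); a value < 1 is a fraction of p; otherwise a count.
resolve_mtry <- function(mtry, p) {
  if (is.null(mtry)) return(max(1L, floor(sqrt(p))))
  if (mtry < 1) max(1L, floor(mtry * p)) else min(as.integer(mtry), p)
}

# LDA prior: NULL = empirical; a scalar is P(class 1); else a length-2 vector.
resolve_prior <- function(prior, y) {
  if (is.null(prior)) {
    as.numeric(table(factor(y, levels = c(0, 1))) / length(y))
  } else if (length(prior) == 1) {
    c(1 - prior, prior)
  } else prior
}

fit_ridge_logistic <- function(xs, y, lambda) {
  if (ncol(xs) == 1) {
    # glmnet requires >= 2 columns; pad with a constant that gets coefficient 0
    xs <- cbind(xs, 0)
  }
  # glmnet warns ("dangerous ground") whenever a class has < 8 subjects,
  # which is routine for the small cohorts this package targets
  withCallingHandlers(
    glmnet::glmnet(xs, y, family = "binomial", alpha = 0, lambda = lambda,
                   standardize = FALSE),
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w))) invokeRestart("muffleWarning")
    }
  )
}

fit_svm <- function(xs, y, hp) {
  e1071::svm(
    x = xs, y = factor(y, levels = c(0, 1)), kernel = hp$kernel,
    cost = hp$cost, gamma = hp$gamma %||% 1 / ncol(xs), scale = FALSE
  )
}

#' Score subjects with a trained model
#'
#' @param model A `trained_model`.
#' @param x Numeric matrix with the same columns as at training time; `NA`
#'   entries are imputed with the training-fold medians.
#' @return Numeric vector of class-1 scores in [0, 1], one per row.
#' @export
predict_scores <- function(model, x) {
  stopifnot(inherits(model, "trained_model"))
  x <- as.matrix(x)
  if (ncol(x) != model$p) {
    abort(paste0("x has ", ncol(x), " columns but the model was trained on ", model$p))
  }
  xs <- apply_preprocessor(model$prep, x)
  fam <- model$spec$family
  s <- switch(fam,
    NN = mlp_predict(model$fit, xs),
    XGB = as.numeric(stats::predict(model$fit, xgboost::xgb.DMatrix(xs))),
    RF = as.numeric(stats::predict(model$fit, data = xs, num.threads = 1)$predictions[, "1"]),
    LR = {
      xp <- if (ncol(xs) == 1) cbind(xs, 0) else xs
      as.numeric(stats::predict(model$fit, newx = xp, type = "response"))
    },
    SVM = {
      pred <- stats::predict(model$fit, xs, decision.values = TRUE)
      d <- attr(pred, "decision.values")
      # column name "A/B": positive margin favours class A
      pos_first <- startsWith(colnames(d)[1], "1/")
      as.numeric(stats::plogis(if (pos_first) d[, 1] else -d[, 1]))
    },
    LDA = {
      keep <- model$extra$lda_keep
      as.numeric(stats::predict(model$fit, xs[, keep, drop = FALSE])$posterior[, "1"])
    }
  )
  pmin(pmax(s, 0), 1)
}
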