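#' Model-agnostic Shapley attributions
#'
#' Attributes a trained model's score for each explained subject to the
#' individual features via Shapley values: features absent from a coalition
#' are replaced by values drawn from a background set (here, typically the
#' training fold). Two estimators are available:
#'
#' * `"exact"` (p <= 12): enumerates all 2^p coalitions; the value of a
#'   coalition is the mean model score with the out-of-coalition entries
#'   replaced by each background row in turn. Satisfies local accuracy to
#'   machine precision: `base_value + rowSums(phi)` equals the model score.
#' * `"sampling"`: permutation-walk estimator. Each walk draws one random
#'   feature permutation and one background row, then switches features from
#'   background to instance values in permutation order; the score change at
#'   each switch is one marginal-contribution sample for that feature. One
#'   walk costs p + 1 model evaluations, so `budget` coalition evaluations
#'   per instance buy `ceiling(budget / (p + 1))` walks (at least one).
#'
#' All model evaluations are batched into a single [predict_scores()] call
#' per instance set, so the estimator is fast for the wide matrices typical
#' of untargeted metabolomics.
#'
#' @param model A `trained_model`.
#' @param background Numeric matrix of background subjects (same columns as
#'   training).
#' @param instances Numeric matrix of subjects to explain.
#' @param budget Coalition evaluations per instance for the sampling
#'   estimator (default 128).
#' @param seed Integer seed for the sampling estimator.
#' @param method `"auto"` (exact when p <= 12, else sampling), `"exact"`, or
#'   `"sampling"`.
#' @return A numeric matrix (instances x features) of attributions, with
#'   attributes `base_value` (mean model score over the background rows) and
#'   `method`.
#' @export
shapley_attributions <- function(model, background, instances, budget = 128L,
                                 seed = 1L, method = c("auto", "exact", "sampling")) {
  method <- match.arg(method)
  background <- as.matrix(background)
  instances <- as.matrix(instances)
  if (nrow(background) == 0) abort("background must be non-empty")
  p <- ncol(instances)
  if (ncol(background) != p) abort("background and instances must share columns")
  if (method == "auto") method <- if (p <= 12) "exact" else "sampling"
  if (method == "exact" && p > 12) abort("exact Shapley is limited to p <= 12")

  base_value <- mean(predict_scores(model, background))
  phi <- if (method == "exact") {
    shap_exact(model, background, instances)
  } else {
    shap_sampling(model, background, instances, budget, seed)
  }
  dimnames(phi) <- list(rownames(instances), colnames(instances))
  attr(phi, "base_value") <- base_value
  attr(phi, "method") <- method
  phi
}

shap_exact <- function(model, background, instances) {
  p <- ncol(instances)
  nb <- nrow(background)
  masks <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), p)))[, seq_len(p), drop = FALSE]
  sizes <- rowSums(masks)
  # Shapley weight for adding feature i to a coalition of size s (excluding i)
  w <- factorial(seq(0, p - 1)) * factorial(p - seq(0, p - 1) - 1) / factorial(p)

  t(apply(instances, 1, function(x) {
    # v(S) = mean over background rows of f(x_S, b_~S)
    big <- matrix(NA_real_, nrow(masks) * nb, p)
    for (b in seq_len(nb)) {
      block <- sweep(masks, 2, x, `*`) +
        sweep(!masks, 2, background[b, ], `*`)
      big[(b - 1) * nrow(masks) + seq_len(nrow(masks)), ] <- block
    }
    vals <- predict_scores(model, big)
    v <- rowMeans(matrix(vals, nrow(masks), nb))
    # index coalitions by their bitmask for O(1) lookup of S vs S + {i}
    key <- as.integer(masks %*% 2^(seq_len(p) - 1))
    v_by_key <- numeric(2^p)
    v_by_key[key + 1L] <- v
    phi <- numeric(p)
    for (i in seq_len(p)) {
      without <- which(!masks[, i])
      s <- sizes[without]
      k0 <- key[without]
      phi[i] <- sum(w[s + 1] * (v_by_key[k0 + 2^(i - 1) + 1L] - v_by_key[k0 + 1L]))
    }
    phi
  }))
}

shap_sampling <- function(model, background, instances, budget, seed) {
  p <- ncol(instances)
  ni <- nrow(instances)
  nb <- nrow(background)
  n_walks <- max(1L, ceiling(budget / (p + 1)))
  with_seed(seed, {
    phi <- matrix(0, ni, p)
    for (k in seq_len(n_walks)) {
      # one permutation and one background row per (walk, instance)
      perms <- purrr::map(seq_len(ni), ~ sample.int(p))
      brow <- sample.int(nb, ni, replace = TRUE)
      # build all walk states: for each instance, p + 1 rows
      big <- matrix(NA_real_, ni * (p + 1), p)
      for (j in seq_len(ni)) {
        z <- matrix(background[brow[j], ], p + 1, p, byrow = TRUE)
        xj <- instances[j, ]
        pj <- perms[[j]]
        for (t in seq_len(p)) {
          z[(t + 1):(p + 1), pj[t]] <- xj[pj[t]]
        }
        big[(j - 1) * (p + 1) + seq_len(p + 1), ] <- z
      }
      vals <- predict_scores(model, big)
      for (j in seq_len(ni)) {
        f <- vals[(j - 1) * (p + 1) + seq_len(p + 1)]
        contrib <- diff(f)
        phi[j, perms[[j]]] <- phi[j, perms[[j]]] + contrib
      }
    }
    phi / n_walks
  })
}

#' Aggregate attribution matrices into per-feature importance scores
#'
#' The global importance of a feature is the absolute average of its
#' attributions over all resampling iterations and all explained subjects:
#' `mean |phi_ij|` (`mode = "mean_abs"`, the standard global-importance
#' reduction). The alternative reading — absolute value of the mean, which
#' cancels opposing effects — is available as `mode = "abs_mean"`.
#'
#' @param attribution_matrices A list of attribution matrices sharing the
#'   same feature columns (e.g. the `$attributions` of a bootstrap result),
#'   or a single matrix.
#' @param mode `"mean_abs"` (default) or `"abs_mean"`.
#' @return A named numeric vector of non-negative per-feature scores.
#' @export
aggregate_shap <- function(attribution_matrices, mode = c("mean_abs", "abs_mean")) {
  mode <- match.arg(mode)
  if (is.matrix(attribution_matrices)) attribution_matrices <- list(attribution_matrices)
  cols <- purrr::map(attribution_matrices, colnames)
  if (length(unique(purrr::map_chr(cols, paste, collapse = "\r"))) > 1) {
    abort("attribution matrices disagree on their feature sets")
  }
  stacked <- do.call(rbind, attribution_matrices)
  if (mode == "mean_abs") colMeans(abs(stacked)) else abs(colMeans(stacked))
}

#' Regulation direction of each feature
#'
#' The direction is the sign of the Pearson correlation between the feature's
#' abundance and the binary label: positive correlation means the feature is
#' up-regulated in the case class. Features with zero or undefined variance
#' get direction `"none"`.
#'
#' @inheritParams run_evaluation
#' @return A tibble with `feature_id`, `correlation`, `direction`
#'   (`"up"`/`"down"`/`"none"`).
#' @export
regulation_direction <- function(data, label = "label") {
  validate_feature_table(data, label = label)
  y <- data[[label]]
  feats <- ft_feature_cols(data, label)
  cors <- purrr::map_dbl(feats, function(f) {
    v <- data[[f]]
    ok <- !is.na(v)
    if (sum(ok) < 3 || stats::sd(v[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
    stats::cor(v[ok], y[ok])
  })
  tibble(
    feature_id = feats,
    correlation = cors,
    direction = dplyr::case_when(
      is.na(cors) | cors == 0 ~ "none",
      cors > 0 ~ "up",
      TRUE ~ "down"
    )
  )
}

#' Rank features by aggregated attribution score
#'
#' @param scores Named numeric vector of non-negative importance scores (see
#'   [aggregate_shap()]).
#' @param directions Optional tibble from [regulation_direction()].
#' @param top_k Number of top features of interest (the full ranking is
#'   always returned; rows beyond `top_k` have `top = FALSE`).
#' @return A tibble of class `feature_ranking` with `feature_id`,
#'   `shap_score`, `rank`, `direction`, `top`, sorted by descending score;
#'   ties broken by feature position (stable).
#' @export
rank_features <- function(scores, directions = NULL, top_k = 10L) {
  if (top_k < 1) abort("top_k must be >= 1")
  ord <- order(-scores, seq_along(scores))
  out <- tibble(
    feature_id = names(scores)[ord],
    shap_score = unname(scores[ord]),
    rank = seq_along(scores),
    top = seq_along(scores) <= top_k
  )
  if (!is.null(directions)) {
    out <- dplyr::left_join(out, directions[c("feature_id", "direction")],
                            by = "feature_id")
  } else {
    out$direction <- NA_character_
  }
  class(out) <- c("feature_ranking", class(out))
  out
}
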