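#' @importFrom ggplot2 autoplot ggplot aes geom_boxplot geom_col geom_line
#'   geom_abline coord_flip labs theme_minimal
#' @export
ggplot2::autoplot

#' Box plot of per-iteration metrics
#'
#' @param object A `bootstrap_result`.
#' @param metrics Metrics to show.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bootstrap_result
#' @export
autoplot.bootstrap_result <- function(object,
                                      metrics = c("accuracy", "precision",
                                                  "sensitivity", "specificity",
                                                  "f1", "mcc", "auc_roc",
                                                  "auc_pr"),
                                      ...) {
  d <- tidy(object) |> dplyr::filter(.data$metric %in% metrics)
  ggplot(d, aes(x = .data$metric, y = .data$value)) +
    geom_boxplot(outlier.size = 0.6) +
    labs(x = NULL, y = "value",
         title = paste0(object$spec$family, ": ", object$plan$n_iterations,
                        " resampling iterations")) +
    theme_minimal()
}

#' Pooled out-of-fold ROC curve
#'
#' Pools every iteration's test-fold predictions into one set and draws the
#' overall ROC curve (labeled as pooled; per-iteration AUCs live in
#' `$metrics`).
#'
#' @param result A `bootstrap_result`.
#' @return A ggplot.
#' @export
plot_pooled_roc <- function(result) {
  roc <- roc_curve_auc(result$pooled$label, result$pooled$score)
  ggplot(roc$curve, aes(x = .data$fpr, y = .data$tpr)) +
    geom_line() +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    labs(x = "false positive rate", y = "true positive rate",
         title = sprintf("Pooled out-of-fold ROC (AUC = %.3f)", roc$auc)) +
    theme_minimal()
}

#' Bar chart of the top-ranked features
#'
#' @param object A `feature_ranking`.
#' @param top_k Number of features to draw (defaults to the ranking's `top`
#'   flag).
#' @param ... Unused.
#' @return A ggplot with bars coloured by regulation direction.
#' @method autoplot feature_ranking
#' @export
autoplot.feature_ranking <- function(object, top_k = NULL, ...) {
  d <- as_tibble(object)
  d <- if (is.null(top_k)) dplyr::filter(d, .data$top) else utils::head(d, top_k)
  d$feature_id <- factor(d$feature_id, levels = rev(d$feature_id))
  ggplot(d, aes(x = .data$feature_id, y = .data$shap_score,
                fill = .data$direction)) +
    geom_col() +
    coord_flip() +
    labs(x = NULL, y = "mean |Shapley attribution|", fill = "direction") +
    theme_minimal()
}
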