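#' Confusion matrix from scores
#'
#' Scores at or above `threshold` predict the positive class (label 1); the
#' boundary counts as positive by convention.
#'
#' @param labels Binary 0/1 vector.
#' @param scores Numeric score vector of the same length.
#' @param threshold Decision threshold (default 0.5).
#' @return A one-row tibble with integer columns `TP`, `FN`, `FP`, `TN`.
#' @export
confusion <- function(labels, scores, threshold = 0.5) {
  if (length(labels) != length(scores)) abort("labels and scores differ in length")
  assert_binary_labels(labels, require_both = FALSE)
  pred <- as.integer(scores >= threshold)
  tibble(
    TP = sum(pred == 1L & labels == 1L),
    FN = sum(pred == 0L & labels == 1L),
    FP = sum(pred == 1L & labels == 0L),
    TN = sum(pred == 0L & labels == 0L)
  )
}

#' Classification metrics from a confusion matrix
#'
#' Computes accuracy, precision, sensitivity (recall), specificity, F1 and the
#' Matthews correlation coefficient. Any metric whose denominator is zero is
#' `NA` (undefined), except MCC which is 0 by convention so that MCC-based
#' model selection stays total.
#'
#' @param cm A one-row tibble/list with `TP`, `FN`, `FP`, `TN`.
#' @return A one-row tibble with the six metrics.
#' @export
metric_vector <- function(cm) {
  TP <- cm$TP; FN <- cm$FN; FP <- cm$FP; TN <- cm$TN
  n <- TP + FN + FP + TN
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  mcc_den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  tibble(
    accuracy = safe_div(TP + TN, n),
    precision = safe_div(TP, TP + FP),
    sensitivity = safe_div(TP, TP + FN),
    specificity = safe_div(TN, TN + FP),
    f1 = safe_div(2 * TP, 2 * TP + FP + FN),
    mcc = if (mcc_den == 0) 0 else (TP * TN - FP * FN) / mcc_den
  )
}

# threshold sweep shared by ROC and PR: descending unique scores, cumulative
# counts of positives/negatives predicted positive at each cut
sweep_thresholds <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  keep <- c(diff(sc) != 0, TRUE)  # last index of each tied score group
  tibble(
    threshold = sc[keep],
    tp = cumsum(lab == 1L)[keep],
    fp = cumsum(lab == 0L)[keep]
  )
}

#' ROC curve and AUC
#'
#' Curve points come from the full threshold sweep; the AUC is the trapezoidal
#' area, equal to the Mann-Whitney pair statistic with ties counted one half.
#'
#' @inheritParams confusion
#' @return A list with `curve` (tibble `fpr`, `tpr`, `threshold`) and `auc`.
#' @export
roc_curve_auc <- function(labels, scores) {
  assert_binary_labels(labels)
  sw <- sweep_thresholds(labels, scores)
  P <- sum(labels == 1L); N <- sum(labels == 0L)
  curve <- tibble(
    fpr = c(0, sw$fp / N), tpr = c(0, sw$tp / P),
    threshold = c(Inf, sw$threshold)
  )
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
  list(curve = curve, auc = auc)
}

#' Precision-recall curve and AUC
#'
#' Precision-recall points at every threshold of the sweep; the AUC is the
#' trapezoid over recall (matching the ROC treatment, not interpolated average
#' precision). The curve is anchored at recall 0 with the precision of the
#' highest-score cut.
#'
#' @inheritParams confusion
#' @return A list with `curve` (tibble `recall`, `precision`, `threshold`)
#'   and `auc`.
#' @export
pr_curve_auc <- function(labels, scores) {
  assert_binary_labels(labels, require_both = FALSE)
  P <- sum(labels == 1L)
  if (P == 0) abort("at least one positive label is required")
  sw <- sweep_thresholds(labels, scores)
  prec <- sw$tp / (sw$tp + sw$fp)
  rec <- sw$tp / P
  curve <- tibble(
    recall = c(0, rec), precision = c(prec[1], prec),
    threshold = c(Inf, sw$threshold)
  )
  auc <- sum(diff(curve$recall) *
               (utils::head(curve$precision, -1) + utils::tail(curve$precision, -1)) / 2)
  list(curve = curve, auc = auc)
}

#' Aggregate per-iteration metrics into mean and standard deviation
#'
#' Summarises the bootstrap iterations metric by metric: mean and sample
#' (n-1) standard deviation over the *defined* values; undefined (`NA`)
#' iterations are excluded and counted, never propagated.
#'
#' @param metric_rows A tibble with one row per iteration and one numeric
#'   column per metric (e.g. the `$metrics` element of a bootstrap result).
#' @return A tibble with columns `metric`, `mean`, `sd`, `n`, `n_undefined`.
#' @export
aggregate_metrics <- function(metric_rows) {
  if (nrow(metric_rows) < 2) abort("need at least two iterations to aggregate")
  metric_rows |>
    dplyr::select(dplyr::where(is.numeric)) |>
    dplyr::select(-dplyr::any_of("iteration")) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(
      mean = if (all(is.na(.data$value))) NA_real_ else mean(.data$value, na.rm = TRUE),
      sd = if (all(is.na(.data$value))) NA_real_ else stats::sd(.data$value, na.rm = TRUE),
      n = sum(!is.na(.data$value)),
      n_undefined = sum(is.na(.data$value)),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$metric, c("accuracy", "precision", "sensitivity",
                                         "specificity", "f1", "mcc",
                                         "auc_roc", "auc_pr")))
}

#' Pooled relative standard deviation across metrics
#'
#' Averages, over the summarised metrics, the per-metric relative standard
#' deviation (sd / mean) x 100; metrics with undefined or zero mean are
#' skipped. A single dispersion number for "how stable was this model across
#' resamples".
#'
#' @param summary A tibble as returned by [aggregate_metrics()].
#' @return Pooled RSD in percent.
#' @export
pooled_rsd <- function(summary) {
  ok <- !is.na(summary$mean) & summary$mean != 0 & !is.na(summary$sd)
  if (!any(ok)) abort("no metric with a defined nonzero mean")
  mean(summary$sd[ok] / summary$mean[ok] * 100)
}
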