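#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a bootstrap result
#'
#' One row per (iteration, metric) pair in long format, ready for plotting or
#' further summarising.
#'
#' @param x A `bootstrap_result`.
#' @param ... Unused.
#' @return A tibble with `iteration`, `metric`, `value`.
#' @method tidy bootstrap_result
#' @export
tidy.bootstrap_result <- function(x, ...) {
  x$metrics |>
    tidyr::pivot_longer(-"iteration", names_to = "metric", values_to = "value") |>
    dplyr::mutate(family = x$spec$family, .before = 1)
}

#' Glance at a bootstrap result
#'
#' @param x A `bootstrap_result`.
#' @param ... Unused.
#' @return A one-row tibble: family, iterations, mean/sd of MCC and both
#'   AUCs, pooled RSD across metrics.
#' @method glance bootstrap_result
#' @export
glance.bootstrap_result <- function(x, ...) {
  s <- x$summary
  pick <- function(m, col) s[[col]][s$metric == m]
  tibble(
    family = x$spec$family,
    n_iterations = x$plan$n_iterations,
    mcc_mean = pick("mcc", "mean"), mcc_sd = pick("mcc", "sd"),
    auc_roc_mean = pick("auc_roc", "mean"), auc_roc_sd = pick("auc_roc", "sd"),
    auc_pr_mean = pick("auc_pr", "mean"), auc_pr_sd = pick("auc_pr", "sd"),
    accuracy_mean = pick("accuracy", "mean"),
    pooled_rsd = pooled_rsd(s)
  )
}

#' Tidy a feature ranking
#'
#' @param x A `feature_ranking`.
#' @param ... Unused.
#' @return The underlying tibble.
#' @method tidy feature_ranking
#' @export
tidy.feature_ranking <- function(x, ...) {
  as_tibble(x)
}
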