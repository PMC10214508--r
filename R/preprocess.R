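# Leakage-free preprocessing: median imputation then per-feature z-scoring,
# with all statistics learned on the training fold only. Zero-variance
# features get scale 1 so downstream learners see a constant 0 column.

fit_preprocessor <- function(x) {
  med <- apply(x, 2, stats::median, na.rm = TRUE)
  med[is.na(med)] <- 0  # feature entirely missing in this fold
  ximp <- impute_with(x, med)
  center <- colMeans(ximp)
  scale <- apply(ximp, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(median = med, center = center, scale = scale)
}

impute_with <- function(x, med) {
  idx <- which(is.na(x), arr.ind = TRUE)
  if (nrow(idx)) x[idx] <- med[idx[, 2]]
  x
}

apply_preprocessor <- function(prep, x) {
  x <- impute_with(x, prep$median)
  scale(x, center = prep$center, scale = prep$scale)[, , drop = FALSE]
}
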