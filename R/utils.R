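#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

# Run code under a local, seeded RNG stream without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Derive a child seed from a parent seed and a stream index; stays below 2^31.
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 214783) %% 2147483587L) + 1L
}

is_binary_labels <- function(y) {
  !anyNA(y) && all(y %in% c(0, 1))
}

assert_binary_labels <- function(y, require_both = TRUE) {
  if (!is_binary_labels(y)) {
    abort("labels must be coded 0 (control) / 1 (case) with no missing values")
  }
  if (require_both && length(unique(y)) < 2) {
    abort("both classes must be present")
  }
  invisible(y)
}
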