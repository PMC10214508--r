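#' Specify a synthetic metabolomics dataset
#'
#' Describes a labeled subject-by-feature table with planted biomarkers, used
#' to exercise the whole pipeline without any cohort download. Abundances are
#' log-normal: each feature draws a baseline log-mean once, subjects deviate
#' with log-sd `noise_sigma`, and features inside a correlated block share a
#' latent subject factor with loading `sqrt(correlation_rho)` so that the
#' within-block correlation of log-abundances converges to `correlation_rho`.
#' Planted informative features shift their class-1 log-mean by
#' `log(effect_fold)`, with the shift direction alternating up/down so that
#' direction recovery is testable.
#'
#' @param n_subjects Number of subjects (>= 4).
#' @param n_features Number of chemical features.
#' @param n_informative Number of planted informative features (<= n_features).
#' @param effect_fold Multiplicative abundance shift in the case class (>= 1);
#'   1 means no signal.
#' @param class_balance Proportion of subjects in the case class, in (0, 1).
#' @param block_sizes Optional integer vector of correlated-block sizes summing
#'   to `n_features`; `NULL` makes every feature its own block (independence).
#' @param correlation_rho Within-block correlation of log-abundances, in [0, 1).
#' @param noise_sigma Log-scale subject-level standard deviation (> 0).
#' @param missing_rate Proportion of cells set missing uniformly at random.
#' @param seed Integer seed; the dataset is bit-reproducible from it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_subjects, n_features, n_informative = 0,
                           effect_fold = 1, class_balance = 0.5,
                           block_sizes = NULL, correlation_rho = 0,
                           noise_sigma = 0.5, missing_rate = 0, seed = 1L) {
  if (n_subjects < 4) abort("n_subjects must be at least 4")
  if (n_features < 1) abort("n_features must be positive")
  if (n_informative < 0 || n_informative > n_features) {
    abort("n_informative must lie in [0, n_features]")
  }
  if (effect_fold < 1) abort("effect_fold must be >= 1")
  if (class_balance <= 0 || class_balance >= 1) abort("class_balance must be in (0, 1)")
  if (!is.null(block_sizes)) {
    if (any(block_sizes < 1) || sum(block_sizes) != n_features) {
      abort("block_sizes must be positive and sum to n_features")
    }
  }
  if (correlation_rho < 0 || correlation_rho >= 1) abort("correlation_rho must be in [0, 1)")
  if (noise_sigma <= 0) abort("noise_sigma must be positive")
  if (missing_rate < 0 || missing_rate >= 1) abort("missing_rate must be in [0, 1)")
  structure(
    list(
      n_subjects = as.integer(n_subjects), n_features = as.integer(n_features),
      n_informative = as.integer(n_informative), effect_fold = effect_fold,
      class_balance = class_balance, block_sizes = block_sizes,
      correlation_rho = correlation_rho, noise_sigma = noise_sigma,
      missing_rate = missing_rate, seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic dataset with known planted biomarkers
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `synthetic_dataset` with elements `table` (a
#'   feature-table tibble including the `label` column), `truth` (tibble with
#'   `feature_id` and planted `direction`, `"up"`/`"down"` in the case class),
#'   and `spec`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n_subjects
    p <- spec$n_features
    n_case <- round(spec$class_balance * n)
    n_case <- max(1L, min(n - 1L, n_case))
    y <- sample(c(rep(1L, n_case), rep(0L, n - n_case)))

    feature_ids <- sprintf("f%04d", seq_len(p))
    block_sizes <- spec$block_sizes %||% rep(1L, p)
    block_of <- rep(seq_along(block_sizes), block_sizes)

    base_mu <- stats::rnorm(p, mean = 10, sd = 1.5)
    lambda <- sqrt(spec$correlation_rho)
    factor_load <- sqrt(1 - spec$correlation_rho)

    # latent subject factor per block + independent noise, both log-scale
    Z_block <- matrix(stats::rnorm(n * length(block_sizes)), n, length(block_sizes))
    E <- matrix(stats::rnorm(n * p), n, p)
    L <- sweep(lambda * Z_block[, block_of, drop = FALSE] + factor_load * E,
               2, rep(1, p), `*`) * spec$noise_sigma
    L <- sweep(L, 2, base_mu, `+`)

    truth <- tibble(feature_id = character(0), direction = character(0))
    if (spec$n_informative > 0) {
      planted <- sort(sample.int(p, spec$n_informative))
      direction <- rep(c("up", "down"), length.out = spec$n_informative)
      shift <- ifelse(direction == "up", 1, -1) * log(spec$effect_fold)
      L[y == 1, planted] <- sweep(L[y == 1, planted, drop = FALSE], 2, shift, `+`)
      truth <- tibble(feature_id = feature_ids[planted], direction = direction)
    }

    X <- exp(L)
    if (spec$missing_rate > 0) {
      miss <- which(stats::runif(n * p) < spec$missing_rate)
      X[miss] <- NA_real_
    }

    tbl <- dplyr::bind_cols(
      tibble(subject_id = sprintf("S%03d", seq_len(n)), label = y),
      as_tibble(`colnames<-`(X, feature_ids))
    )
    structure(list(table = tbl, truth = truth, spec = spec),
              class = "synthetic_dataset")
  })
}

#' Write a synthetic dataset as a plain-text fixture
#'
#' Emits `table.csv` (feature table including labels), `labels.csv`,
#' `truth.json` (planted feature IDs and directions) and `spec.json` into
#' `directory`. Reading the files back reproduces the dataset.
#'
#' @param dataset A `synthetic_dataset`.
#' @param directory Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_fixture <- function(dataset, directory) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(dataset$table, file.path(directory, "table.csv"), "csv")
  readr::write_csv(dataset$table[c("subject_id", "label")],
                   file.path(directory, "labels.csv"))
  jsonlite::write_json(
    purrr::transpose(as.list(dataset$truth)),
    file.path(directory, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  sp <- unclass(dataset$spec)
  sp$block_sizes <- sp$block_sizes %||% NULL
  jsonlite::write_json(sp, file.path(directory, "spec.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(directory)
}
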