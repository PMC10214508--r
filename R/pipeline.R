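#' Pipeline configuration
#'
#' Bundles every knob of a full run: either input files (feature table and
#' optional compound database) or a synthetic-data spec, the model family or
#' grid, the resampling plan, the attribution budget, and the annotation
#' settings. Exactly one of `table_path` and `synthetic` must be given.
#'
#' @param table_path Path to a CSV/TSV feature table with a label column, or
#'   `NULL` when `synthetic` is given.
#' @param synthetic A [synthetic_spec()], or `NULL` when `table_path` is
#'   given.
#' @param compound_db Optional path to a compound TSV for the annotation
#'   stage (features must then be named by their m/z, possibly block-prefixed).
#' @param spec A [model_spec()] (ignored when `grid` is given, beyond its
#'   family defaults).
#' @param grid Optional [hyper_grid()]; when present the pipeline tunes by
#'   mean MCC first and evaluates the winning spec.
#' @param plan A [bootstrap_plan()].
#' @param label Label column name.
#' @param attributions Compute Shapley attributions and a feature ranking?
#' @param shap_budget Coalition evaluations per explained subject.
#' @param top_k Number of top-ranked features reported (and annotated).
#' @param adduct_mode `"positive"` or `"negative"`.
#' @param tolerance_ppm Annotation matching tolerance.
#' @param output_dir Run directory for all output files.
#' @param seed Global seed recorded in the manifest.
#' @return An object of class `run_config`.
#' @export
run_config <- function(table_path = NULL, synthetic = NULL, compound_db = NULL,
                       spec = model_spec("NN"), grid = NULL,
                       plan = bootstrap_plan(), label = "label",
                       attributions = TRUE, shap_budget = 128L, top_k = 10L,
                       adduct_mode = "positive", tolerance_ppm = 20,
                       output_dir = tempfile("mzclass_run_"), seed = 1L) {
  if (is.null(table_path) == is.null(synthetic)) {
    abort("exactly one of table_path and synthetic must be given")
  }
  if (!is.null(table_path) && !file.exists(table_path)) {
    abort(paste0("no such file: ", table_path))
  }
  if (!is.null(compound_db) && !file.exists(compound_db)) {
    abort(paste0("no such file: ", compound_db))
  }
  structure(
    list(table_path = table_path, synthetic = synthetic,
         compound_db = compound_db, spec = spec, grid = grid, plan = plan,
         label = label, attributions = isTRUE(attributions),
         shap_budget = as.integer(shap_budget), top_k = as.integer(top_k),
         adduct_mode = adduct_mode, tolerance_ppm = tolerance_ppm,
         output_dir = output_dir, seed = as.integer(seed)),
    class = "run_config"
  )
}

# feature IDs that parse as m/z values, tolerating a "BLOCK:" prefix
feature_mz <- function(feature_ids) {
  stripped <- sub("^[^:]*:", "", feature_ids)
  suppressWarnings(as.numeric(stripped))
}

#' Run the full pipeline
#'
#' Executes (optional) simulate, (optional) tune, evaluate, interpret and
#' annotate stages, writes all outputs under `config$output_dir`, and returns
#' a manifest sufficient to re-execute the run bit-identically. Outputs:
#' `metrics.csv` (per-iteration), `summary.csv` (mean +/- sd), `ranking.csv`,
#' `annotations.csv` (when a compound DB is configured), `roc_curve.csv` /
#' `pr_curve.csv` (pooled out-of-fold curves), `report.md`, `manifest.json`.
#'
#' @param config A [run_config()].
#' @return A list of class `run_result`: `result` (the `bootstrap_result`),
#'   `ranking`, `annotations`, `tuning`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  started <- format(Sys.time(), tz = "UTC")
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  data <- if (!is.null(config$synthetic)) {
    generate_dataset(config$synthetic)$table
  } else {
    fmt <- if (grepl("\\.tsv$", config$table_path)) "tsv" else "csv"
    read_feature_table(config$table_path, fmt, label_column = config$label)
  }

  tuning <- NULL
  spec <- config$spec
  if (!is.null(config$grid)) {
    tuning <- grid_search(data, config$grid, config$plan, label = config$label)
    spec <- tuning$best_spec
  }

  result <- run_evaluation(data, spec, config$plan, label = config$label,
                           attributions = config$attributions,
                           shap_budget = config$shap_budget)

  ranking <- NULL
  if (config$attributions) {
    scores <- aggregate_shap(result$attributions)
    dirs <- regulation_direction(data, label = config$label)
    ranking <- rank_features(scores, dirs, top_k = config$top_k)
  }

  annotations <- NULL
  if (!is.null(config$compound_db) && !is.null(ranking)) {
    db <- read_compound_table(config$compound_db)
    top <- dplyr::filter(as_tibble(ranking), .data$top)
    mzs <- feature_mz(top$feature_id)
    ok <- !is.na(mzs)
    annotations <- if (any(ok)) {
      annotate_mz(mzs[ok], db, adduct_set(config$adduct_mode),
                  config$tolerance_ppm)
    } else {
      annotate_mz(numeric(0), db, adduct_set(config$adduct_mode),
                  config$tolerance_ppm)
    }
  }

  out <- config$output_dir
  readr::write_csv(result$metrics, file.path(out, "metrics.csv"))
  readr::write_csv(result$summary, file.path(out, "summary.csv"))
  roc <- roc_curve_auc(result$pooled$label, result$pooled$score)
  pr <- pr_curve_auc(result$pooled$label, result$pooled$score)
  readr::write_csv(roc$curve, file.path(out, "roc_curve.csv"))
  readr::write_csv(pr$curve, file.path(out, "pr_curve.csv"))
  if (!is.null(ranking)) readr::write_csv(as_tibble(ranking), file.path(out, "ranking.csv"))
  if (!is.null(annotations)) readr::write_csv(annotations, file.path(out, "annotations.csv"))

  report_path <- file.path(out, "report.md")
  write_report(result, ranking, annotations, report_path)

  files <- c("metrics.csv", "summary.csv", "roc_curve.csv", "pr_curve.csv",
             if (!is.null(ranking)) "ranking.csv",
             if (!is.null(annotations)) "annotations.csv", "report.md")
  manifest <- list(
    tool = paste0("mzclass ", as.character(utils::packageVersion("mzclass"))),
    started_utc = started, finished_utc = format(Sys.time(), tz = "UTC"),
    seed = config$seed, plan = unclass(config$plan),
    family = spec$family, hyperparameters = spec$hyperparameters,
    label = config$label,
    input = if (!is.null(config$table_path)) {
      list(path = config$table_path,
           md5 = unname(tools::md5sum(config$table_path)))
    } else {
      list(synthetic = unclass(config$synthetic))
    },
    outputs = files
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  structure(list(result = result, ranking = ranking,
                 annotations = annotations, tuning = tuning,
                 manifest = manifest, output_dir = out),
            class = "run_result")
}

#' Write a human-readable run report
#'
#' A short markdown summary: the per-metric mean +/- sd table, the pooled
#' RSD, the top-ranked features with directions, and (when present) their
#' annotations.
#'
#' @param result A `bootstrap_result`.
#' @param ranking Optional `feature_ranking`.
#' @param annotations Optional annotation tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, ranking = NULL, annotations = NULL,
                         path = "report.md") {
  s <- result$summary
  lines <- c(
    "# Classification run report",
    "",
    sprintf("Model family: **%s** — %d resampling iterations (train fraction %.2f).",
            result$spec$family, result$plan$n_iterations,
            result$plan$train_fraction),
    "",
    "## Diagnostic performance (mean ± sd over iterations)",
    "",
    "| metric | mean | sd | undefined iterations |",
    "|---|---|---|---|",
    sprintf("| %s | %.3f | %.3f | %d |", s$metric, s$mean, s$sd, s$n_undefined),
    "",
    sprintf("Pooled relative standard deviation across metrics: %.1f%%.",
            pooled_rsd(s))
  )
  if (!is.null(ranking)) {
    top <- dplyr::filter(as_tibble(ranking), .data$top)
    lines <- c(lines, "", "## Top-ranked features", "")
    if (nrow(top) == 0) {
      lines <- c(lines, "No features ranked.")
    } else {
      lines <- c(lines,
                 "| rank | feature | SHAP score | direction |",
                 "|---|---|---|---|",
                 sprintf("| %d | %s | %.4g | %s |", top$rank, top$feature_id,
                         top$shap_score, top$direction))
    }
  }
  if (!is.null(annotations)) {
    lines <- c(lines, "", "## Annotations", "")
    if (nrow(annotations) == 0) {
      lines <- c(lines, "No compound matched within tolerance.")
    } else {
      lines <- c(lines,
                 "| observed m/z | compound | adduct | theoretical m/z | ppm | exogenous? |",
                 "|---|---|---|---|---|---|",
                 sprintf("| %.4f | %s | %s | %.4f | %+.1f | %s |",
                         annotations$observed_mz, annotations$compound_name,
                         annotations$adduct, annotations$theoretical_mz,
                         annotations$ppm,
                         ifelse(annotations$exogenous_flag, "yes", "no")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
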