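#' Feature tables
#'
#' A feature table is a plain tibble holding one untargeted-metabolomics run:
#' one row per subject, a `subject_id` character column, an optional binary
#' `label` column (1 = case, 0 = control), and one numeric column per chemical
#' feature. Feature IDs are free-form strings and are often m/z values printed
#' to four decimals. Missing abundances are `NA`, never zero: imputation is the
#' evaluation engine's job, performed per training fold.
#'
#' @param data A feature-table tibble.
#' @param label Name of the label column, or `NULL` if the table is unlabeled.
#' @name feature_table
NULL

ft_feature_cols <- function(data, label = "label") {
  setdiff(names(data), c("subject_id", label))
}

ft_matrix <- function(data, label = "label") {
  feats <- ft_feature_cols(data, label)
  m <- as.matrix(data[feats])
  storage.mode(m) <- "double"
  rownames(m) <- data$subject_id
  m
}

#' Validate a feature table
#'
#' Checks the structural invariants: unique subject IDs, unique feature IDs,
#' numeric abundances that are finite where present, and (if a label column is
#' present) labels coded 0/1.
#'
#' @inheritParams feature_table
#' @return `data`, invisibly, if valid; otherwise an error.
#' @export
validate_feature_table <- function(data, label = "label") {
  if (!is.data.frame(data)) abort("feature table must be a data frame")
  if (!"subject_id" %in% names(data)) abort("feature table needs a `subject_id` column")
  if (anyDuplicated(data$subject_id)) abort("duplicate subject IDs")
  feats <- ft_feature_cols(data, label)
  if (length(feats) == 0) abort("feature table has no feature columns")
  if (anyDuplicated(feats)) abort("duplicate feature IDs")
  for (f in feats) {
    v <- data[[f]]
    if (!is.numeric(v)) abort(paste0("feature column `", f, "` is not numeric"))
    if (any(!is.finite(v) & !is.na(v))) abort(paste0("feature column `", f, "` has non-finite values"))
  }
  if (!is.null(label) && label %in% names(data)) {
    assert_binary_labels(data[[label]], require_both = FALSE)
  }
  invisible(data)
}

#' Read a subject-by-feature table from CSV/TSV
#'
#' The first column of the file is taken as the subject ID, an optional
#' `label_column` carries the 0/1 class label, and every remaining column is a
#' feature. Empty cells and the token `NA` are read as missing; any other
#' non-numeric abundance is an error.
#'
#' @param path Path to a delimited text file with a header row.
#' @param format `"csv"` or `"tsv"`.
#' @param label_column Optional name of the label column.
#' @return A feature-table tibble (label column retained when present).
#' @export
read_feature_table <- function(path, format = c("csv", "tsv"), label_column = "label") {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  reader <- if (format == "csv") readr::read_csv else readr::read_tsv
  raw <- reader(path, col_types = readr::cols(.default = readr::col_character()),
                na = character(), name_repair = "minimal", progress = FALSE)
  hdr <- names(raw)
  if (anyDuplicated(hdr)) abort("duplicate column (feature) IDs in header")
  names(raw)[1] <- "subject_id"
  feats <- setdiff(names(raw), c("subject_id", label_column))
  for (f in feats) {
    v <- raw[[f]]
    v[v %in% c("", "NA")] <- NA_character_
    num <- suppressWarnings(as.numeric(v))
    bad <- !is.na(v) & is.na(num)
    if (any(bad)) {
      abort(paste0("non-numeric abundance in feature `", f, "`: '", v[bad][1], "'"))
    }
    raw[[f]] <- num
  }
  if (!is.null(label_column) && label_column %in% names(raw)) {
    raw[[label_column]] <- as.integer(raw[[label_column]])
  }
  out <- as_tibble(raw)
  validate_feature_table(out, label = label_column)
  out
}

#' Write a feature table to CSV/TSV
#'
#' Missing abundances are written as empty cells so that
#' `read_feature_table()` round-trips the table exactly, including missing-cell
#' positions.
#'
#' @inheritParams feature_table
#' @param path Output file path.
#' @param format `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(data, path, format = c("csv", "tsv"), label = "label") {
  format <- match.arg(format)
  validate_feature_table(data, label = label)
  writer <- if (format == "csv") readr::write_csv else readr::write_tsv
  writer(data, path, na = "")
  invisible(path)
}

#' Merge instrument blocks into a composite feature table
#'
#' Untargeted studies often analyse the same cohort on several instrument
#' platforms (e.g. GC-MS, CE-MS, LC-MS in both ionisation modes). The
#' composite table keeps only subjects present in *every* block — a subject
#' missing from one or more platforms is excluded — and concatenates all
#' blocks' features. Feature IDs are prefixed with their block tag
#' (`"GC-MS:105.0421"`) because different platforms can report the same m/z.
#'
#' @param tables A named list of feature-table tibbles; names are the block
#'   tags. Unnamed lists get tags `"block1"`, `"block2"`, ...
#' @param label Name of the label column (taken from the first block that has
#'   one; labels must agree across blocks for shared subjects).
#' @return A composite feature-table tibble.
#' @export
merge_composite <- function(tables, label = "label") {
  if (!is.list(tables) || length(tables) == 0) abort("need at least one block")
  tags <- names(tables) %||% rep("", length(tables))
  tags[tags == ""] <- paste0("block", seq_along(tables))[tags == ""]
  if (anyDuplicated(tags)) abort("block tags must be unique")
  purrr::walk(tables, validate_feature_table, label = label)

  subjects <- purrr::reduce(purrr::map(tables, ~ .x$subject_id), intersect)
  if (length(subjects) == 0) abort("no subject is present in every block")

  labs <- NULL
  pieces <- purrr::map2(tables, tags, function(tbl, tag) {
    tbl <- tbl[match(subjects, tbl$subject_id), , drop = FALSE]
    if (!is.null(label) && label %in% names(tbl)) {
      if (is.null(labs)) labs <<- tbl[[label]]
      else if (!identical(as.integer(labs), as.integer(tbl[[label]]))) {
        abort("label disagreement across blocks for shared subjects")
      }
    }
    feats <- ft_feature_cols(tbl, label)
    out <- tbl[feats]
    names(out) <- paste0(tag, ":", feats)
    out
  })

  out <- dplyr::bind_cols(tibble(subject_id = subjects), pieces)
  if (!is.null(labs)) out <- dplyr::mutate(out, label = as.integer(labs), .after = "subject_id")
  validate_feature_table(out, label = label)
  out
}

#' Per-feature block tags of a composite table
#'
#' @inheritParams feature_table
#' @return A tibble with `feature_id` and `block` (NA for unprefixed features).
#' @export
block_tags <- function(data, label = "label") {
  feats <- ft_feature_cols(data, label)
  has <- grepl(":", feats, fixed = TRUE)
  tibble(
    feature_id = feats,
    block = ifelse(has, sub(":.*$", "", feats), NA_character_)
  )
}
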