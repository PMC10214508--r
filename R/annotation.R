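# Monoisotopic masses of the most abundant isotope (Da), CODATA/IUPAC values.
ISOTOPE_MASS <- c(
  C = 12.0, H = 1.00782503207, N = 14.0030740048, O = 15.99491461956,
  F = 18.99840316273, Na = 22.9897692809, P = 30.97376163, S = 31.97207100,
  Cl = 34.96885268, Br = 78.9183371, I = 126.904473, K = 38.96370668
)

ELECTRON_MASS <- 0.00054857990907

PROTON <- ISOTOPE_MASS[["H"]] - ELECTRON_MASS   #  1.00727645
WATER <- 2 * ISOTOPE_MASS[["H"]] + ISOTOPE_MASS[["O"]]

#' Ionisation adducts
#'
#' The supported adduct hypotheses, with mass deltas that include the
#' electron mass (a protonated ion is `M + H - e`): `[M+H]+` (+1.007276 Da),
#' `[M+Na]+` (+22.989221 Da), `[M+H-H2O]+` (-17.003289 Da), `[M-H]-`
#' (-1.007276 Da). The default set depends on the ionisation mode: positive
#' mode covers protonation, sodiation and water loss; negative mode,
#' deprotonation.
#'
#' @param mode `"positive"`, `"negative"`, or `"all"`.
#' @return A tibble with `adduct`, `delta` (Da), `charge`.
#' @export
adduct_set <- function(mode = c("positive", "negative", "all")) {
  mode <- match.arg(mode)
  all <- tibble(
    adduct = c("[M+H]+", "[M+Na]+", "[M+H-H2O]+", "[M-H]-"),
    delta = c(PROTON,
              ISOTOPE_MASS[["Na"]] - ELECTRON_MASS,
              PROTON - WATER,
              -PROTON),
    charge = c(1L, 1L, 1L, -1L)
  )
  switch(mode,
    positive = all[all$charge > 0, ],
    negative = all[all$charge < 0, ],
    all = all
  )
}

#' Parse a molecular formula
#'
#' Accepts plain Hill-style formulas (`"C21H8F28O8"`, count 1 may be
#' omitted) and tolerates underscore or unicode-subscript decorated counts as
#' they appear in typeset tables (`"C_21_H_8_F_28_O_8_"`).
#'
#' @param text Formula string.
#' @return A named integer vector of element counts.
#' @export
parse_formula <- function(text) {
  clean <- gsub("[_ ]", "", text)
  subs <- c("₀","₁","₂","₃","₄","₅","₆","₇","₈","₉")
  for (i in seq_along(subs)) clean <- gsub(subs[i], as.character(i - 1), clean, fixed = TRUE)
  if (!nzchar(clean)) abort("empty formula")
  tokens <- regmatches(clean, gregexpr("([A-Z][a-z]?)([0-9]*)", clean))[[1]]
  if (sum(nchar(tokens)) != nchar(clean)) {
    abort(paste0("malformed formula: '", text, "'"))
  }
  el <- sub("[0-9]*$", "", tokens)
  cnt <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                           sub("^[A-Za-z]+", "", tokens), "1"))
  unknown <- setdiff(el, names(ISOTOPE_MASS))
  if (length(unknown)) {
    abort(paste0("unsupported element(s): ", paste(unknown, collapse = ", ")))
  }
  counts <- tapply(cnt, factor(el, levels = unique(el)), sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  if (all(out == 0)) abort("formula has no atoms")
  out
}

#' Monoisotopic mass of a formula
#'
#' Sum of count times the mass of each element's most abundant isotope
#' (carbon-12 is exactly 12 by definition).
#'
#' @param formula A named count vector from [parse_formula()], or a formula
#'   string.
#' @return Neutral monoisotopic mass in Da.
#' @export
monoisotopic_mass <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  sum(ISOTOPE_MASS[names(formula)] * formula)
}

#' Theoretical m/z of an adduct ion
#'
#' @param neutral_mass Neutral monoisotopic mass in Da (> 0).
#' @param adduct Adduct name (a row of [adduct_set()]), e.g. `"[M+Na]+"`.
#' @return Theoretical m/z = (mass + delta) / |charge|.
#' @export
adduct_mz <- function(neutral_mass, adduct) {
  if (neutral_mass <= 0) abort("neutral mass must be positive")
  tbl <- adduct_set("all")
  row <- tbl[tbl$adduct == adduct, ]
  if (nrow(row) == 0) abort(paste0("unknown adduct: ", adduct))
  mz <- (neutral_mass + row$delta) / abs(row$charge)
  if (mz <= 0) abort("resulting m/z is not positive")
  mz
}

#' Signed relative mass error in parts per million
#'
#' @param observed Observed m/z.
#' @param theoretical Theoretical m/z (> 0).
#' @return `(observed - theoretical) / theoretical * 1e6`.
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) abort("theoretical m/z must be positive")
  (observed - theoretical) / theoretical * 1e6
}

#' Mass defect and exogenous-compound flag
#'
#' The mass defect is the signed distance of an m/z value to its nearest
#' integer. Heavily fluorinated synthetic compounds (e.g. PFAS) show strongly
#' negative mass defects, unlike CHNO-dominated endogenous metabolites whose
#' defect grows positive with mass. The flag marks defects below
#' `-0.0015 Da per 100 Da` of m/z — a documented, configurable heuristic
#' calibrated so that a heavily fluorinated ion near 943 Da (defect about
#' -0.018) is flagged while small ions with near-zero defect are not.
#'
#' @param mz Observed m/z (> 0).
#' @param threshold_per_100da Flagging slope in Da per 100 Da (default
#'   -0.0015).
#' @return A tibble with `mz`, `defect`, `exogenous_flag`.
#' @export
mass_defect <- function(mz, threshold_per_100da = -0.0015) {
  if (any(mz <= 0)) abort("m/z must be positive")
  defect <- mz - round(mz)
  tibble(mz = mz, defect = defect,
         exogenous_flag = defect < threshold_per_100da * mz / 100)
}

#' Read a local compound table
#'
#' A plain TSV snapshot standing in for a compound database, with columns
#' `id`, `name`, `formula`. Monoisotopic masses are computed and cached in a
#' `mass` column.
#'
#' @param path Path to the TSV file.
#' @return A tibble with `id`, `name`, `formula`, `mass`.
#' @export
read_compound_table <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  db <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  need <- c("id", "name", "formula")
  if (!all(need %in% names(db))) abort("compound table needs columns id, name, formula")
  db$mass <- purrr::map_dbl(db$formula, monoisotopic_mass)
  as_tibble(db[c("id", "name", "formula", "mass")])
}

#' Annotate an observed m/z against a compound table
#'
#' Tests every (compound, adduct) pair and keeps those whose theoretical m/z
#' lies within `tolerance_ppm` of the observation. Matches are sorted by
#' absolute ppm error (ties by compound id), and each carries the observed
#' ion's mass defect and exogenous flag.
#'
#' @param observed_mz Observed m/z value(s).
#' @param db Compound tibble from [read_compound_table()].
#' @param adducts Adduct tibble (default positive-mode set of [adduct_set()]).
#' @param tolerance_ppm Matching half-window in ppm (default 20).
#' @return A tibble with one row per retained (observed m/z, compound,
#'   adduct) match: `observed_mz`, `compound_id`, `compound_name`, `formula`,
#'   `adduct`, `theoretical_mz`, `ppm`, `mass_defect`, `exogenous_flag`.
#' @export
annotate_mz <- function(observed_mz, db, adducts = adduct_set("positive"),
                        tolerance_ppm = 20) {
  if (nrow(db) == 0) abort("compound table is empty")
  if (tolerance_ppm <= 0) abort("tolerance must be positive")
  if (!"mass" %in% names(db)) db$mass <- purrr::map_dbl(db$formula, monoisotopic_mass)
  cand <- tidyr::crossing(
    tibble(observed_mz = observed_mz),
    tidyr::crossing(db[c("id", "name", "formula", "mass")], adducts)
  )
  cand <- cand |>
    dplyr::mutate(
      theoretical_mz = (.data$mass + .data$delta) / abs(.data$charge),
      ppm = ppm_error(.data$observed_mz, .data$theoretical_mz)
    ) |>
    dplyr::filter(abs(.data$ppm) <= tolerance_ppm) |>
    dplyr::arrange(.data$observed_mz, abs(.data$ppm), .data$id)
  md <- mass_defect(cand$observed_mz)
  cand |>
    dplyr::transmute(
      observed_mz = .data$observed_mz,
      compound_id = .data$id, compound_name = .data$name,
      formula = .data$formula, adduct = .data$adduct,
      theoretical_mz = .data$theoretical_mz, ppm = .data$ppm,
      mass_defect = md$defect, exogenous_flag = md$exogenous_flag
    )
}
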