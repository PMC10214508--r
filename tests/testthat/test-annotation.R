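# the five printed (m/z, formula, ion) annotation triples used as fixtures
annotation_rows <- tibble::tribble(
  ~observed, ~formula,      ~ion,
  942.9824,  "C21H8F28O8",  "[M+Na]+",
  467.3822,  "C30H52O2",    "[M+Na]+",
  613.4767,  "C37H66O5",    "[M+Na]+",
  379.3289,  "C28H44O",     "[M+H-H2O]+",
  393.3454,  "C27H46",      "[M+Na]+"
)

test_that("formula parsing handles plain and underscore-decorated notation", {
  expect_equal(parse_formula("C21H8F28O8"),
               c(C = 21L, H = 8L, F = 28L, O = 8L))
  expect_equal(parse_formula("C_21_H_8_F_28_O_8_"),
               c(C = 21L, H = 8L, F = 28L, O = 8L))
  expect_equal(parse_formula("H2O"), c(H = 2L, O = 1L))
  expect_equal(parse_formula("C27H46"), c(C = 27L, H = 46L))
  expect_equal(parse_formula("NaCl"), c(Na = 1L, Cl = 1L))
  expect_error(parse_formula("C2Xx3"), "unsupported")
  expect_error(parse_formula("21C"), "malformed")
})

test_that("monoisotopic masses match tabulated isotope sums and are additive", {
  expect_equal(monoisotopic_mass("H2O"), 18.010565, tolerance = 1e-6)
  expect_equal(monoisotopic_mass("C27H46"), 370.359951, tolerance = 1e-6)
  expect_equal(monoisotopic_mass(c(C = 1L)), 12.0)  # carbon-12 definition
  # additivity over formula concatenation
  expect_equal(monoisotopic_mass("C6H12O6") + monoisotopic_mass("H2O"),
               monoisotopic_mass("C6H14O7"), tolerance = 1e-10)
})

test_that("adduct m/z deltas are proton/electron-exact", {
  M <- 500
  expect_equal(adduct_mz(M, "[M+H]+") - M, 1.007276, tolerance = 1e-6)
  expect_equal(adduct_mz(M, "[M+Na]+") - M, 22.989221, tolerance = 1e-6)
  expect_equal(adduct_mz(M, "[M+H-H2O]+") - M, -17.003289, tolerance = 1e-6)
  expect_equal(adduct_mz(M, "[M-H]-") - M, -1.007276, tolerance = 1e-6)
  expect_equal(adduct_mz(919.977206, "[M+Na]+"), 942.966426, tolerance = 1e-6)
  expect_equal(adduct_mz(396.339216, "[M+H-H2O]+"), 379.335928, tolerance = 1e-6)
  expect_error(adduct_mz(-1, "[M+H]+"), "positive")
  expect_error(adduct_mz(1, "[M+Zz]+"), "unknown")
})

test_that("ppm error is the definitional relative deviation", {
  expect_equal(ppm_error(942.9824, 942.966426), 16.94, tolerance = 0.01)
  expect_equal(ppm_error(500, 500), 0)
  x <- 873.2
  expect_equal(ppm_error(x * (1 + 2e-5), x), 20, tolerance = 1e-9)
})

test_that("all five printed annotation triples fall within the 20 ppm window", {
  ppms <- purrr::pmap_dbl(annotation_rows, function(observed, formula, ion) {
    ppm_error(observed, adduct_mz(monoisotopic_mass(formula), ion))
  })
  expect_true(all(abs(ppms) <= 20))
  # the water-loss (vitamin D2) row is the least accurate of the five
  expect_equal(which.max(abs(ppms)), 4L)
  # the fluorinated row passes on its own
  expect_lte(abs(ppms[1]), 20)
})

test_that("mass defect flags strongly negative-defect ions only", {
  md <- mass_defect(c(942.9824, 467.3822, 100))
  expect_equal(md$defect, c(-0.0176, 0.3822, 0), tolerance = 1e-4)
  expect_equal(md$exogenous_flag, c(TRUE, FALSE, FALSE))
})

test_that("annotation against the packaged compound table recovers the printed matches", {
  db <- read_compound_table(system.file("extdata", "compounds_demo.tsv",
                                        package = "mzclass"))
  expect_equal(nrow(db), 10L)
  hits <- annotate_mz(942.9824, db)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$formula, "C21H8F28O8")
  expect_equal(hits$adduct, "[M+Na]+")
  expect_true(hits$exogenous_flag)

  for (i in seq_len(nrow(annotation_rows))) {
    h <- annotate_mz(annotation_rows$observed[i], db)
    expect_true(annotation_rows$formula[i] %in% h$formula)
    expect_true(annotation_rows$ion[i] %in% h$adduct[h$formula == annotation_rows$formula[i]])
  }

  expect_equal(nrow(annotate_mz(123.456, db)), 0L)  # far from everything
})

test_that("matches are sorted by absolute ppm and respect the adduct mode", {
  db <- tibble::tibble(id = c("a", "b"), name = c("close", "closer"),
                       formula = c("C10H20O2", "C10H20O2"))
  db$mass <- purrr::map_dbl(db$formula, monoisotopic_mass)
  mz <- adduct_mz(db$mass[1], "[M+H]+") * (1 + 3e-6)
  h <- annotate_mz(mz, db, tolerance_ppm = 10)
  expect_equal(h$compound_id, c("a", "b"))  # tie broken by id
  expect_true(all(abs(h$ppm) <= 10))

  neg <- adduct_set("negative")
  expect_equal(neg$adduct, "[M-H]-")
  h_neg <- annotate_mz(db$mass[1] - 1.007276, db, adducts = neg, tolerance_ppm = 5)
  expect_equal(nrow(h_neg), 2L)
})

test_that("tightening the tolerance never adds matches", {
  db <- read_compound_table(system.file("extdata", "compounds_demo.tsv",
                                        package = "mzclass"))
  withr::with_seed(91, {
    for (rep in 1:20) {
      mz <- runif(1, 100, 1000)
      wide <- nrow(annotate_mz(mz, db, tolerance_ppm = 50))
      narrow <- nrow(annotate_mz(mz, db, tolerance_ppm = 10))
      expect_lte(narrow, wide)
    }
  })
})

test_that("dual-direction search agrees: neutralised observation vs adduct-shifted compound", {
  db <- read_compound_table(system.file("extdata", "compounds_demo.tsv",
                                        package = "mzclass"))
  adducts <- adduct_set("positive")
  withr::with_seed(92, {
    mzs <- c(runif(10, 100, 1000), 942.9824, 393.3454)
  })
  for (mz in mzs) {
    forward <- annotate_mz(mz, db, adducts)
    # reverse direction: neutralise the observation under each adduct and
    # compare neutral masses on the same relative scale
    rev_hits <- purrr::pmap(adducts, function(adduct, delta, charge) {
      neutral <- mz * abs(charge) - delta
      ok <- abs((neutral - db$mass) / (db$mass + delta)) * 1e6 <= 20
      tibble::tibble(compound_id = db$id[ok], adduct = adduct)
    })
    rev_hits <- dplyr::bind_rows(rev_hits)
    expect_setequal(paste(forward$compound_id, forward$adduct),
                    paste(rev_hits$compound_id, rev_hits$adduct))
  }
})
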