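test_that("monoisotopic masses match hand-summed reference values", {
  # 2 * 1.00782503207 + 15.994915
  expect_equal(formula_monoisotopic_mass("H2O"), 18.0105646, tolerance = 1e-6)
  expect_equal(formula_monoisotopic_mass("C15H14O6"), 290.0790380,
               tolerance = 1e-6)
  expect_equal(formula_monoisotopic_mass("C6H12O6"),
               6 * 12 + 12 * 1.00782503207 + 6 * 15.994915, tolerance = 1e-9)
  # grouped elements accumulate
  expect_equal(formula_monoisotopic_mass("CH3COOH"),
               formula_monoisotopic_mass("C2H4O2"), tolerance = 1e-12)
})

test_that("malformed formulas are rejected", {
  expect_error(formula_monoisotopic_mass(""), "empty")
  expect_error(formula_monoisotopic_mass("C15H14O6X"), "X")
  expect_error(formula_monoisotopic_mass("Xy12"), "Xy")
  expect_error(formula_monoisotopic_mass("C0H2"), "positive")
})

test_that("adduct shifts derive from the atomic mass table", {
  tab <- adduct_table()
  shift <- function(a) tab$mass_shift[tab$adduct == a]
  expect_equal(shift("M+H"), 1.007276, tolerance = 1e-6)
  expect_equal(shift("M-H"), -1.007276, tolerance = 1e-6)
  expect_equal(shift("M+Na"), 22.989218, tolerance = 1e-6)
  expect_equal(shift("M+NH4"), 18.033823, tolerance = 1e-6)
  expect_equal(shift("M+AcOH-H"), 59.013851, tolerance = 1e-5)
  expect_equal(shift("M+"), -0.00054858, tolerance = 1e-9)
})

test_that("adduct m/z computation is exact and invertible", {
  catechin <- formula_monoisotopic_mass("C15H14O6")
  expect_equal(adduct_mz(catechin, "M+H"), 291.0863, tolerance = 1e-4)
  expect_equal(adduct_mz(catechin, "M-H"), 289.0718, tolerance = 1e-4)
  m <- 412.34567
  expect_equal(adduct_mz(m, "M+H") - adduct_table()$mass_shift[1], m,
               tolerance = 1e-12)
  expect_error(adduct_mz(catechin, "M-H", mode = "positive"),
               "not a positive-mode")
  expect_error(adduct_mz(-1, "M+H"), "positive")
})

test_that("matching respects the ppm tolerance boundary", {
  db <- wine_compounds()
  catechin_mh <- adduct_mz(formula_monoisotopic_mass("C15H14O6"), "M-H")
  mk <- function(ppm) {
    ints <- matrix(1, 1, 2, dimnames = list(NULL, c("S1", "S2")))
    feature_table("f1", mz = catechin_mh * (1 + ppm * 1e-6), rt = 5, ints,
                  mode = "negative")
  }
  hit <- annotate_features(mk(4.9), db, tol_ppm = 5)
  expect_true("catechin" %in% hit$candidates$compound)
  expect_equal(hit$candidates$ppm_error[hit$candidates$compound == "catechin"],
               4.9, tolerance = 1e-6)
  miss <- annotate_features(mk(5.1), db, tol_ppm = 5)
  expect_false("catechin" %in% miss$candidates$compound)
  exact <- annotate_features(mk(0), db, tol_ppm = 5)
  expect_equal(max(abs(exact$candidates$ppm_error[
    exact$candidates$compound == "catechin"])), 0, tolerance = 1e-9)
})

test_that("tolerance monotonicity: candidates at 3 ppm are a subset of 5 ppm", {
  ds <- generate_dataset(small_config(seed = 8, annotation_ppm_offset = 2.5))
  a3 <- annotate_features(ds$feature_table, ds$compound_db, tol_ppm = 3)
  a5 <- annotate_features(ds$feature_table, ds$compound_db, tol_ppm = 5)
  key <- function(a) paste(a$candidates$feature_id, a$candidates$compound,
                           a$candidates$adduct)
  expect_true(all(key(a3) %in% key(a5)))
})

test_that("zero-offset planted features are recovered at 0 ppm", {
  ds <- generate_dataset(small_config(seed = 9))
  ann <- annotate_features(ds$feature_table, ds$compound_db, tol_ppm = 5)
  planted <- ds$ground_truth$planted_compounds
  cand_key <- paste(ann$candidates$feature_id, ann$candidates$compound,
                    ann$candidates$adduct)
  for (i in seq_len(nrow(planted))) {
    k <- paste(planted$feature_id[i], planted$compound[i], planted$adduct[i])
    expect_true(k %in% cand_key)
  }
  hit <- ann$candidates[cand_key %in% paste(planted$feature_id,
                                            planted$compound,
                                            planted$adduct), ]
  expect_equal(max(abs(hit$ppm_error)), 0, tolerance = 1e-8)
})

test_that("intrinsic cations match only as M+ in positive mode", {
  db <- wine_compounds()
  pelargonidin <- db[db$name == "pelargonidin 3-O-glucoside", ]
  mz_cation <- formula_monoisotopic_mass(pelargonidin$formula) - 0.00054858
  ints <- matrix(1, 1, 2, dimnames = list(NULL, c("S1", "S2")))
  tab <- feature_table("f1", mz = mz_cation, rt = 5, ints, mode = "positive")
  ann <- annotate_features(tab, db, tol_ppm = 5)
  hit <- ann$candidates[ann$candidates$compound == pelargonidin$name, ]
  expect_equal(hit$adduct, "M+")
  # in negative mode the cation is not a candidate at all
  tabneg <- feature_table("f1", mz = mz_cation, rt = 5, ints,
                          mode = "negative")
  annneg <- annotate_features(tabneg, db, tol_ppm = 5)
  expect_false(pelargonidin$name %in% annneg$candidates$compound)
})

test_that("MSI levels follow the single-formula / single-class rule", {
  cand <- function(...) {
    rows <- list(...)
    data.frame(formula = vapply(rows, `[[`, "", 1),
               compound_class = vapply(rows, `[[`, "", 2))
  }
  expect_equal(assign_msi_level(cand(c("C15H14O6", "flavanol"))), 2L)
  # same formula twice (catechin/epicatechin): still a single formula
  expect_equal(assign_msi_level(cand(c("C15H14O6", "flavanol"),
                                     c("C15H14O6", "flavanol"))), 2L)
  expect_equal(assign_msi_level(cand(c("C21H21O11", "anthocyanin"),
                                     c("C22H23O10", "anthocyanin"))), 3L)
  expect_equal(assign_msi_level(cand(c("C21H21O11", "anthocyanin"),
                                     c("C15H14O6", "flavanol"))), 4L)
  expect_equal(assign_msi_level(NULL), 4L)
  # empty database: every feature is level 4
  empty_db <- data.frame(name = character(0), formula = character(0),
                         compound_class = character(0),
                         intrinsic_charge = numeric(0))
  ann <- annotate_features(tiny_table(), empty_db)
  expect_true(all(ann$msi_levels$msi_level == 4L))
})
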