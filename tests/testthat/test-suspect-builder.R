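# Suspect-list curation: raw CSV loading, salt stripping, ionizability,
# list building with rejects bookkeeping.

test_that("raw lists load from the template schema only", {
  path <- write_raw_csv(c("C8HF17O3S", "C8HF15O2", "C6F14"),
                        `pKa acidic` = c(-3.3, 0.5, NA),
                        `QC level` = c(1L, 2L, 3L))
  rec <- load_raw_list(path)
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$pka_acidic, c(-3.3, 0.5, NA))
  expect_equal(rec$qc_level, c(1L, 2L, 3L))
  # wrong first-column label is a schema error
  bad <- write_raw_csv("C8HF17O3S", first_col = "Formula")
  expect_error(load_raw_list(bad), "Molecular formula",
               class = "pfscreen_schema_error")
  # salt dot notation is loaded verbatim and flagged at build time
  salt <- load_raw_list(write_raw_csv("C8HF17O3S.Na"))
  expect_true(grepl("\\.", salt$formula_text))
})

test_that("counter-ion stripping collapses salts onto the free-acid mass", {
  acid <- strip_counterion("C8HF17O3S")
  expect_false(acid$is_salt)
  salt <- strip_counterion("C8F17O3S.K")
  expect_true(salt$is_salt)
  expect_equal(salt$counterion, "K")
  expect_equal(format_formula(salt$anion), "C8F17O3S")
  # bit-identical charged masses for the salt and the free acid
  expect_identical(charged_mass(monoisotopic_mass(salt$neutral)),
                   charged_mass(monoisotopic_mass(acid$neutral)))
  # unrecognised counter-ion (tetrabutylammonium): warning + neutral fallback
  expect_warning(tba <- strip_counterion("C8F17O3S.C16H36N"),
                 "unrecognised")
  expect_true(is.na(tba$counterion))
  expect_equal(tba$neutral[["N"]], 1L)  # merged composition kept
})

test_that("ionizability classes follow the pKa presence rules", {
  expect_equal(classify_ionizability(-3.3, NA), "acidic")
  expect_equal(classify_ionizability(NA, 9.1), "electropositive")
  expect_equal(classify_ionizability(NA, NA), "non_ionizable")
  expect_equal(classify_ionizability(c(-3.3, NA, NA), c(NA, 9.1, NA)),
               c("acidic", "electropositive", "non_ionizable"))
})

test_that("list building recomputes masses and links isotopologues", {
  rec <- load_raw_list(write_raw_csv("C8HF17O3S", `pKa acidic` = -3.3))
  sl <- build_suspect_list(rec)
  expect_equal(sl$entries$charged_mass, 498.93022, tolerance = 1e-5)
  # one monoisotopic row plus one per isotopologue element (C, O, S)
  expect_equal(nrow(sl$long), 4L)
  expect_setequal(sl$long$label, c("mono", "13C", "34S", "18O"))
  expect_true(all(sl$long$parent_id == sl$entries$id))
  # isotopologue rows carry the parent-linked charged mass
  o18 <- sl$long[sl$long$label == "18O", ]
  expect_equal(o18$charged_mass, 500.93446, tolerance = 1e-5)
})

test_that("row conservation: accepted + rejected = input, rows reported", {
  path <- write_raw_csv(c("C8HF17O3S", "C8HFl17O3S", "C4HF9", "notaformula",
                          "C6F14"))
  sl <- build_suspect_list(load_raw_list(path))
  expect_equal(nrow(sl$entries) + nrow(sl$rejects), 5L)
  expect_equal(nrow(sl$rejects), 2L)
  expect_match(sl$rejects$reason[1], "Fl")
  # long table = one mono row per accepted entry + all isotopologues
  n_iso <- sum(vapply(sl$entries$isotopologues, nrow, integer(1)))
  expect_equal(nrow(sl$long), nrow(sl$entries) + n_iso)
  # duplicate ids refuse to build
  dup <- load_raw_list(write_raw_csv(c("CH4", "C2H6"), id = c("a", "a")))
  expect_error(build_suspect_list(dup), "duplicate",
               class = "pfscreen_data_error")
})

test_that("rebuilding a list from its own export is idempotent", {
  raw <- write_raw_csv(c("C8HF17O3S", "C8F17O3S.K", "C6F14"),
                       id = c("pfos", "pfos-k", "pfhx"),
                       `pKa acidic` = c(-3.3, -3.3, NA),
                       `QC level` = c(1L, 2L, 3L))
  sl1 <- build_suspect_list(load_raw_list(raw))
  out <- tempfile(fileext = ".csv")
  write_raw_list(sl1, out)
  sl2 <- build_suspect_list(load_raw_list(out))
  expect_equal(sl2$entries$charged_mass, sl1$entries$charged_mass)
  expect_equal(sl2$entries$formula, sl1$entries$formula)
  expect_equal(sl2$entries$is_salt, sl1$entries$is_salt)
  expect_equal(sl2$long$relative_abundance, sl1$long$relative_abundance)
})

test_that("the long-format export leads with the Molecular formula column", {
  sl <- build_suspect_list(load_raw_list(write_raw_csv("C8HF17O3S")))
  path <- tempfile(fileext = ".csv")
  write_suspect_list(sl, path)
  header <- names(utils::read.csv(path, check.names = FALSE, nrows = 1))
  expect_equal(header[1], "Molecular formula")
})
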