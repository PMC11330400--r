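# Exact-mass chemistry engine: parsing, monoisotopic and isotopologue
# masses, ion arithmetic, descriptors, Kendrick analysis.

test_that("formula parsing reads Hill strings and round-trips", {
  expect_equal(parse_formula("C8HF17O3S"),
               c(C = 8L, H = 1L, F = 17L, O = 3L, S = 1L))
  expect_equal(parse_formula("C11H6Cl2F6N2"),
               c(C = 11L, H = 6L, Cl = 2L, F = 6L, N = 2L))
  # repeated symbols accumulate; canonical formatting restores Hill order
  expect_equal(parse_formula("CH3CH2OH"), c(C = 2L, H = 6L, O = 1L))
  expect_equal(format_formula(parse_formula("O3SC8HF17")), "C8HF17O3S")
  expect_equal(format_formula(parse_formula("H2O")), "H2O")
})

test_that("formula parsing rejects unknown elements and malformed input", {
  expect_error(parse_formula("C8HFl17O3S"), "Fl",
               class = "pfscreen_data_error")
  expect_error(parse_formula(""), class = "pfscreen_data_error")
  expect_error(parse_formula("C8H$2"), class = "pfscreen_data_error")
  expect_error(parse_formula("8C"), class = "pfscreen_data_error")
})

test_that("monoisotopic masses reproduce printed reference values", {
  expect_equal(monoisotopic_mass("C11H6Cl2F6N2"), 349.98122, tolerance = 1e-7)
  expect_equal(monoisotopic_mass("C6H2F12O3"), 349.98123, tolerance = 1e-7)
  # independent hand summation: 2 * 1.0078250319 + 15.9949146221
  expect_equal(monoisotopic_mass("H2O"), 18.01056, tolerance = 1e-5)
})

test_that("monoisotopic mass is additive over disjoint formula merges", {
  set.seed(11)
  pool <- c("C", "H", "N", "O", "F", "S", "Cl", "Br", "Si", "P")
  for (rep in 1:25) {
    e1 <- sample(pool, 4)
    e2 <- setdiff(pool, e1)[1:3]
    f1 <- setNames(sample(1:20, 4, replace = TRUE), e1)
    f2 <- setNames(sample(1:20, 3, replace = TRUE), e2)
    merged <- parse_formula(paste0(format_formula(f1), format_formula(f2)))
    expect_equal(monoisotopic_mass(merged),
                 monoisotopic_mass(f1) + monoisotopic_mass(f2),
                 tolerance = 1e-12)
  }
})

test_that("deprotonation applies the 1.007277 Da constant and round-trips", {
  pfos <- monoisotopic_mass("C8HF17O3S")
  expect_equal(pfos, 499.93749, tolerance = 1e-5)
  expect_equal(charged_mass(pfos), 498.93022, tolerance = 1e-5)
  # identity ion form leaves an already-charged mass unchanged
  expect_identical(charged_mass(pfos, ion_form("M-")), pfos)
  expect_error(charged_mass(0.5), class = "pfscreen_data_error")
  expect_error(charged_mass(-1, ion_form("none")),
               class = "pfscreen_data_error")
  # round trip: charged + proton constant restores the neutral mass exactly
  expect_equal(charged_mass(pfos) + 1.007277, pfos, tolerance = 1e-12)
})

test_that("single-substitution isotopologues cover exactly C,S,O,Cl,Br,Si", {
  iso <- isotopologues("C8HF17O3S")
  expect_setequal(iso$label, c("13C", "34S", "18O"))
  o18 <- iso[iso$label == "18O", ]
  expect_equal(charged_mass(monoisotopic_mass("C8HF17O3S")) + o18$mass_shift,
               500.93446, tolerance = 1e-5)
  # 13C relative abundance = count * 0.0107 / 0.9893
  c13 <- iso[iso$label == "13C", ]
  expect_equal(c13$relative_abundance, 8 * 0.0107 / 0.9893, tolerance = 1e-6)
  # water: only 18O; H never contributes
  expect_equal(isotopologues("H2O")$label, "18O")
  expect_equal(nrow(isotopologues("H2")), 0L)
})

test_that("isotopologue shifts match the isotope table and scale linearly", {
  tab <- isotope_table()
  for (el in c("C", "S", "O", "Cl", "Br", "Si")) {
    f <- setNames(c(3L, 1L), c(el, "F"))
    if (el == "F") next
    iso <- isotopologues(f)
    light <- tab[tab$element == el & tab$principal, ]
    heavy <- tab[tab$element == el & !tab$principal, ]
    heavy <- heavy[which.max(heavy$abundance), ]
    expect_equal(iso$mass_shift, heavy$mass - light$mass, tolerance = 1e-6)
    # relative abundance is linear in the element count
    f2 <- f; f2[el] <- 6L
    expect_equal(isotopologues(f2)$relative_abundance,
                 2 * iso$relative_abundance, tolerance = 1e-12)
  }
})

test_that("descriptors compute ratios, DBE and signed mass defect", {
  d <- descriptors("C8HF17O3S", m = 498.93022)
  expect_equal(d$dbe, 0)  # 1 + 8 - 18/2
  expect_equal(d$f_c, 2.125)
  expect_equal(d$mass_defect, -0.06978, tolerance = 1e-5)
  expect_equal(d$ospn_c, 0.5)
  expect_equal(descriptors("C4F9", m = 218.98566)$ospn_c, 0)
  # no carbon: ratios undefined-flagged, not an error
  expect_true(is.na(descriptors("H2O")$f_c))
  # DBE is integer or half-integer; saturated acyclic alkanes give 0
  set.seed(7)
  for (n in sample(1:30, 5)) {
    alkane <- setNames(c(n, 2L * n + 2L), c("C", "H"))
    expect_equal(descriptors(alkane)$dbe, 0)
  }
  expect_equal(descriptors("C11H6Cl2F6N2")$dbe %% 0.5, 0)
})

test_that("Kendrick normalization maps the base unit to integer mass", {
  cf2 <- monoisotopic_mass("CF2")
  km <- kendrick(cf2)
  expect_equal(km$kendrick_mass, 50, tolerance = 1e-5)
  expect_equal(km$kmd, 0, tolerance = 1e-5)
  expect_equal(kendrick(100)$kendrick_mass, 100 * 50 / cf2, tolerance = 1e-12)
})

test_that("homologs differing by whole CF2 units share a Kendrick defect", {
  base <- charged_mass(monoisotopic_mass("C8HF15O2"))  # PFOA anion
  cf2 <- monoisotopic_mass("CF2")
  kmd0 <- kendrick(base)$kmd
  for (k in 1:5) {
    expect_equal(kendrick(base + k * cf2)$kmd, kmd0, tolerance = 1e-6)
  }
})
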