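# Candidate reduction: dedup, score threshold, pKa and fragment exclusion,
# composite ranking, funnel bookkeeping.

cand_tbl <- function(n = 3, ...) {
  defaults <- tibble::tibble(
    suspect_id = sprintf("S%02d", seq_len(n)),
    theoretical_mz = 400 + seq_len(n),
    measured_mz = 400 + seq_len(n),
    ppm_error = rep(0.5, n),
    intensity = rep(1e6, n),
    snr = rep(50, n),
    window = rep("400-500", n),
    qc_level = rep(1L, n),
    pka_acidic = rep(-3, n),
    pka_basic = rep(NA_real_, n),
    ionizability = rep("acidic", n),
    ospn_c = rep(0.5, n),
    score = rep(100, n),
    level = rep("L4", n))
  args <- list(...)
  for (nm in names(args)) defaults[[nm]] <- args[[nm]]
  defaults
}

test_that("duplicates collapse onto the highest-S/N annotation", {
  # salt and free acid share a bit-identical charged mass on the same peak
  cand <- cand_tbl(2, suspect_id = c("PFOS", "PFOS-K"),
                   theoretical_mz = c(498.93022, 498.93022),
                   snr = c(30, 30))
  dd <- dedup_candidates(cand)
  expect_equal(nrow(dd$kept), 1L)
  expect_equal(dd$kept$suspect_id, "PFOS")  # first on ties
  # window-overlap twin: max S/N wins
  cand2 <- cand_tbl(2, suspect_id = c("A", "A"),
                    theoretical_mz = c(500.1, 500.1), snr = c(30, 12),
                    window = c("400-500", "500-600"))
  expect_equal(dedup_candidates(cand2)$kept$snr, 30)
  # no duplicates: identity, and the split is a partition
  cand3 <- cand_tbl(3)
  dd3 <- dedup_candidates(cand3)
  expect_equal(nrow(dd3$kept), 3L)
  expect_equal(nrow(dd3$kept) + nrow(dd3$removed), nrow(cand3))
})

test_that("the similarity threshold removes only scored candidates", {
  cand <- cand_tbl(4, score = c(100, 80, 74.9, NA),
                   level = c("L4", "L4", "L4", "L5"))
  st <- similarity_threshold(cand, min_score = 75)
  expect_equal(st$kept$score, c(100, 80, NA))
  expect_equal(st$removed$score, 74.9)
  # L5 candidates (no score) always pass; min_score 0 is the identity
  expect_equal(nrow(similarity_threshold(cand, 0)$removed), 0L)
})

test_that("pKa exclusion keeps acids and partitions the exclusions", {
  cand <- cand_tbl(3, ionizability = c("acidic", "non_ionizable",
                                       "electropositive"))
  pk <- pka_exclusion(cand)
  expect_equal(pk$kept$ionizability, "acidic")
  expect_equal(nrow(pk$excluded_non_ionizable), 1L)
  expect_equal(nrow(pk$excluded_electropositive), 1L)
  expect_equal(nrow(pk$kept) + nrow(pk$excluded_non_ionizable) +
                 nrow(pk$excluded_electropositive), nrow(cand))
})

test_that("heteroatom-free candidates are excluded as likely fragments", {
  cand <- cand_tbl(2, suspect_id = c("C4F9-like", "PFOS"),
                   ospn_c = c(0, 0.5))
  fr <- fragment_exclusion(cand)
  expect_equal(fr$kept$suspect_id, "PFOS")
  expect_equal(fr$removed$suspect_id, "C4F9-like")
  empty <- fragment_exclusion(cand[0, ])
  expect_equal(nrow(empty$kept), 0L)
})

test_that("composite ranking averages three min-max normalized variables", {
  cand <- cand_tbl(3, ppm_error = c(0.1, 0.5, 1.0),
                   qc_level = c(1L, 3L, 5L), pka_acidic = c(-3, 0, 3))
  rk <- composite_rank(cand)
  # norms: |ppm| -> (0, 4/9, 1); QC -> (0, 0.5, 1); pKa -> (0, 0.5, 1)
  expect_equal(rk$composite, c(0, (4 / 9 + 0.5 + 0.5) / 3, 1),
               tolerance = 1e-12)
  expect_equal(rk$rank, 1:3)
  # QC endpoints map 1 -> 0 and 5 -> 1
  expect_equal(rk$norm_qc, c(0, 0.5, 1))
  # identical candidates tie and break by charged mass ascending
  tie <- cand_tbl(2, theoretical_mz = c(402, 401))
  rk2 <- composite_rank(tie)
  expect_equal(rk2$theoretical_mz, c(401, 402))
  # degenerate min = max maps to 0, not NaN
  one <- composite_rank(cand_tbl(1))
  expect_equal(one$composite, 0)
})

test_that("composite ranking is invariant to affine rescaling of one input", {
  set.seed(3)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    cand <- cand_tbl(n, ppm_error = runif(n, 0, 1.5),
                     qc_level = sample(1:5, n, replace = TRUE),
                     pka_acidic = rnorm(n, 0, 4))
    rk1 <- composite_rank(cand)
    scaled <- cand
    scaled$pka_acidic <- 2.5 * scaled$pka_acidic + 7  # affine, order-preserving
    rk2 <- composite_rank(scaled)
    expect_equal(rk2$norm_pka, rk1$norm_pka, tolerance = 1e-9)
    expect_equal(rk2$rank, rk1$rank)
  }
})

test_that("missing pKa among ranked candidates warns and normalizes to 1", {
  cand <- cand_tbl(2, pka_acidic = c(-3, NA))
  expect_warning(rk <- composite_rank(cand), "pKa")
  expect_equal(rk$norm_pka[rk$suspect_id == "S02"], 1)
})

test_that("funnel bookkeeping enforces conservation and chaining", {
  ok <- funnel_report(list(
    list(stage = "dedup", n_in = 238, n_removed = 48, n_out = 190),
    list(stage = "similarity", n_in = 190, n_removed = 7, n_out = 183),
    list(stage = "pka_non_ionizable", n_in = 183, n_removed = 64,
         n_out = 119),
    list(stage = "pka_electropositive", n_in = 119, n_removed = 35,
         n_out = 84)))
  expect_equal(ok$n_out[nrow(ok)], 84L)
  expect_true(all(ok$n_in - ok$n_removed == ok$n_out))
  # broken conservation is an internal error (test hook)
  expect_error(funnel_report(list(
    list(stage = "dedup", n_in = 238, n_removed = 48, n_out = 191))),
    class = "pfscreen_internal_error")
  # broken chaining too
  expect_error(funnel_report(list(
    list(stage = "a", n_in = 10, n_removed = 2, n_out = 8),
    list(stage = "b", n_in = 9, n_removed = 1, n_out = 8))),
    class = "pfscreen_internal_error")
  # empty input: an all-zero report validates
  zero <- funnel_report(list(
    list(stage = "dedup", n_in = 0, n_removed = 0, n_out = 0)))
  expect_equal(zero$n_out, 0L)
})

test_that("the offline formula hook returns an empty set for any query", {
  hook <- offline_formula_hook()
  out <- hook(498.93, 1.5)
  expect_s3_class(out, "tbl_df")
  expect_equal(nrow(out), 0L)
})
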