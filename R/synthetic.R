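# Ground-truthed synthetic data: a small suspect list spanning every
# filtering pathway, and simulated CASI peak lists with spiked suspects,
# isotopologue peaks, decoy matrix peaks and blank-overlap peaks.

#' Synthetic suspect list
#'
#' A 29-entry list covering every pathway of the screen: 10 perfluoro-
#' carboxylic acid (PFCA) and 10 perfluoroalkane sulfonic acid (PFSA)
#' homologs as acidic spikes (with synthetic acidic pKa and cycling QC
#' levels), the PFOS potassium salt as a salt/free-acid duplicate, three
#' fully fluorinated non-ionizable alkanes, two basic fluoroamines
#' (electropositive), and three heteroatom-free hydrofluorocarbon fragment
#' surrogates carrying a synthetic acidic pKa so that the in-source
#' fragment filter (not the pKa filter) is what removes them.
#'
#' @inheritParams parse_formula
#' @return A `suspect_list`.
#' @export
synthetic_suspects <- function(isotopes = isotope_table()) {
  pfca_n <- 4:13
  pfsa_n <- 4:13
  rec <- function(formula, id, qc, pka_a = NA_real_, pka_b = NA_real_) {
    tibble::tibble(id = id, formula_text = formula, smiles = NA_character_,
                   inchikey = NA_character_, iupac_name = NA_character_,
                   qc_level = as.integer(qc), pka_acidic = pka_a,
                   pka_basic = pka_b, charge = NA_integer_)
  }
  pfca <- do.call(rbind, lapply(seq_along(pfca_n), function(i) {
    n <- pfca_n[i]
    rec(sprintf("C%dHF%dO2", n, 2 * n - 1), sprintf("PFCA-C%d", n),
        qc = (i - 1L) %% 5L + 1L, pka_a = 0.5 - 0.05 * n)
  }))
  pfsa <- do.call(rbind, lapply(seq_along(pfsa_n), function(i) {
    n <- pfsa_n[i]
    rec(sprintf("C%dHF%dO3S", n, 2 * n + 1), sprintf("PFSA-C%d", n),
        qc = (i - 1L) %% 5L + 1L, pka_a = -3.3)
  }))
  others <- rbind(
    rec("C8F17O3S.K", "PFOS-K", qc = 1L, pka_a = -3.3),
    rec("C6F14", "PFC-6", qc = 3L),
    rec("C8F18", "PFC-8", qc = 3L),
    rec("C10F22", "PFC-10", qc = 4L),
    rec("C6H8F7N", "AMINE-1", qc = 2L, pka_b = 9.5),
    rec("C8H8F9N", "AMINE-2", qc = 4L, pka_b = 9.8),
    rec("C4HF9", "FRAG-C4", qc = 5L, pka_a = 10),
    rec("C6HF13", "FRAG-C6", qc = 5L, pka_a = 10),
    rec("C8HF17", "FRAG-C8", qc = 5L, pka_a = 10)
  )
  build_suspect_list(rbind(pfca, pfsa, others), isotopes)
}

#' Simulation configuration
#'
#' Defines the conditions of a simulated direct-infusion measurement. The
#' defaults are the clean-pattern condition: every suspect of the synthetic
#' list spiked with zero ppm offset and jitter and exact theoretical
#' isotopologue intensities, 200 decoy matrix peaks at least 5 ppm from any
#' suspect signal, and 5 blank-overlap peaks present at equal intensity in
#' sample and blank.
#'
#' @param seed Integer seed fixing all randomness.
#' @param spiked Tibble with columns `id`, `intensity`, `ppm_offset`
#'   (default: all synthetic suspects at intensities 2e5–2e6, offset 0).
#' @param decoy_count Number of decoy matrix peaks.
#' @param decoy_mass_range Decoy m/z range in Da.
#' @param intensity_noise Lognormal sdlog of multiplicative intensity noise.
#' @param ppm_jitter Gaussian sd of mass jitter in ppm.
#' @param windows CASI window bounds.
#' @param overlap Window overlap in Da.
#' @param floor Detection floor in counts; peaks below it are not detected.
#' @param n_blank Number of blank-overlap peaks.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(seed = 1L, spiked = NULL, decoy_count = 200L,
                              decoy_mass_range = c(150, 1000),
                              intensity_noise = 0, ppm_jitter = 0,
                              windows = casi_windows(), overlap = 5,
                              floor = 1e4, n_blank = 5L) {
  if (ppm_jitter < 0 || intensity_noise < 0) {
    stop_schema("noise parameters must be non-negative")
  }
  structure(list(seed = as.integer(seed), spiked = spiked,
                 decoy_count = as.integer(decoy_count),
                 decoy_mass_range = decoy_mass_range,
                 intensity_noise = intensity_noise, ppm_jitter = ppm_jitter,
                 windows = windows, overlap = overlap, floor = floor,
                 n_blank = as.integer(n_blank)),
            class = "sim_config")
}

# Default spike table: every non-salt suspect, intensities log-spaced
# 2e5..2e6. Salt entries are not spiked separately: a salt and its free acid
# are the same anion in solution, so they share one physical peak and the
# salt entry exists to exercise charged-mass deduplication.
default_spikes <- function(suspects) {
  e <- suspects$entries[!suspects$entries$is_salt, ]
  n <- nrow(e)
  tibble::tibble(id = e$id,
                 intensity = 10^seq(log10(2e5), log10(2e6), length.out = n),
                 ppm_offset = 0)
}

#' Simulate a direct-infusion dataset
#'
#' Each spiked suspect contributes its deprotonated monoisotopic peak plus
#' every isotopologue at its theoretical relative abundance, perturbed by
#' Gaussian ppm jitter and lognormal intensity noise; peaks below the
#' detection floor are not reported. Decoy masses are sampled uniformly and
#' rejection-filtered to lie at least 5 ppm from every suspect charged mass
#' and isotopologue position. Peaks are assigned to every CASI window whose
#' extended (±overlap) bounds contain them, reproducing the duplicate
#' retention of spectral stitching. S/N is intensity-proportional with the
#' floor pinned at S/N 4.
#'
#' @param cfg A [simulation_config()].
#' @param suspects A `suspect_list` (default [synthetic_suspects()]).
#' @return A list with `spectra` (one [spectrum()] per window), `blank`
#'   (a spectrum spanning the full range), `truth` (tibble: `mz`,
#'   `intensity`, `role`, `id`, `label`) and `config`.
#' @export
simulate_dataset <- function(cfg = simulation_config(),
                             suspects = synthetic_suspects()) {
  set.seed(cfg$seed)
  spiked <- if (is.null(cfg$spiked)) default_spikes(suspects) else cfg$spiked
  entries <- suspects$entries
  miss <- setdiff(spiked$id, entries$id)
  if (length(miss)) {
    stop_schema("spiked ids not in suspect list: ",
                paste(miss, collapse = ", "))
  }
  wl <- cfg$windows
  in_any_window <- function(mz) {
    any(mz >= wl$lo - cfg$overlap & mz <= wl$hi + cfg$overlap)
  }
  jitter1 <- function(mz, offset) {
    mz * (1 + (offset + stats::rnorm(1L, 0, cfg$ppm_jitter)) * 1e-6)
  }
  noise1 <- function(x) x * exp(stats::rnorm(1L, 0, cfg$intensity_noise))
  rows <- list()
  add <- function(mz, intensity, role, id, label) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      mz = mz, intensity = intensity, role = role, id = id, label = label)
  }
  protected <- numeric(0)  # m/z positions decoys must avoid
  for (i in seq_len(nrow(spiked))) {
    e <- entries[entries$id == spiked$id[i], ]
    if (!in_any_window(e$charged_mass)) {
      stop_schema("spiked mass ", e$charged_mass, " (", e$id,
                  ") lies outside all CASI windows")
    }
    mono_int <- noise1(spiked$intensity[i])
    add(jitter1(e$charged_mass, spiked$ppm_offset[i]), mono_int,
        "spike_mono", e$id, "mono")
    protected <- c(protected, e$charged_mass)
    iso <- e$isotopologues[[1L]]
    for (j in seq_len(nrow(iso))) {
      iso_mz <- e$charged_mass + iso$mass_shift[j]
      protected <- c(protected, iso_mz)
      iso_int <- mono_int * iso$relative_abundance[j]
      if (cfg$intensity_noise > 0) iso_int <- noise1(iso_int)
      if (iso_int < cfg$floor) next  # below the detection floor
      add(jitter1(iso_mz, spiked$ppm_offset[i]), iso_int,
          "isotopologue", e$id, iso$label[j])
    }
  }
  # decoys: uniform masses rejected within 5 ppm of any suspect signal
  n_drawn <- 0L
  while (n_drawn < cfg$decoy_count) {
    mz <- stats::runif(1L, cfg$decoy_mass_range[1L], cfg$decoy_mass_range[2L])
    if (any(abs(mz - protected) / protected * 1e6 < 5)) next
    n_drawn <- n_drawn + 1L
    add(mz, 10^stats::runif(1L, log10(cfg$floor), log10(2e6)), "decoy",
        sprintf("DECOY-%03d", n_drawn), NA_character_)
  }
  # blank-overlap peaks: same mass and intensity in sample and blank
  blank_rows <- list()
  n_b <- 0L
  while (n_b < cfg$n_blank) {
    mz <- stats::runif(1L, cfg$decoy_mass_range[1L], cfg$decoy_mass_range[2L])
    if (any(abs(mz - protected) / protected * 1e6 < 5)) next
    n_b <- n_b + 1L
    int <- 10^stats::runif(1L, log10(cfg$floor * 10), log10(1e6))
    add(mz, int, "blank_overlap", sprintf("BLANK-%02d", n_b), NA_character_)
    blank_rows[[n_b]] <- tibble::tibble(mz = mz, intensity = int,
                                        snr = 4 * int / cfg$floor)
  }
  truth <- do.call(rbind, rows)
  truth <- truth[truth$intensity >= cfg$floor, ]
  truth$snr <- 4 * truth$intensity / cfg$floor
  spectra <- lapply(seq_len(nrow(wl)), function(w) {
    sel <- truth$mz >= wl$lo[w] - cfg$overlap &
      truth$mz <= wl$hi[w] + cfg$overlap
    spectrum(truth[sel, c("mz", "intensity", "snr")],
             wl$lo[w], wl$hi[w], wl$label[w])
  })
  blank_peaks <- do.call(rbind, blank_rows)
  blank <- spectrum(blank_peaks, min(wl$lo), max(wl$hi), "blank")
  list(spectra = spectra, blank = blank, truth = truth, config = cfg)
}

#' Write a simulated dataset to disk
#'
#' Writes one peak-list CSV per CASI window (columns `m/z`, `intensity`,
#' `S/N` — the dialect [read_peaklist()] reads), a blank peak list and the
#' ground-truth table.
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulated_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in sim$spectra) {
    if (nrow(s) == 0L) next  # window with no detected signal
    out <- data.frame(`m/z` = s$mz, intensity = s$intensity, `S/N` = s$snr,
                      check.names = FALSE)
    utils::write.csv(out, file.path(dir, paste0("window_",
                                                attr(s, "label"), ".csv")),
                     row.names = FALSE)
  }
  b <- sim$blank
  utils::write.csv(data.frame(`m/z` = b$mz, intensity = b$intensity,
                              `S/N` = b$snr, check.names = FALSE),
                   file.path(dir, "blank.csv"), row.names = FALSE)
  utils::write.csv(sim$truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
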