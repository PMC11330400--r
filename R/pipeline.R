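# End-to-end screen: spectra -> matching -> isotope scoring -> filtering and
# ranking, with funnel bookkeeping and plot-ready table export.

#' Screening configuration
#'
#' All pipeline defaults in one place: 1.5 ppm mass tolerance, 10 nearest
#' neighbours, S/N >= 4, similarity score >= 75, blank intensity ratio 10,
#' +/- 5 Da CASI overlap, deprotonation ion form.
#'
#' @param tol_ppm Global mass-accuracy tolerance in ppm.
#' @param k Neighbour count for suspect matching.
#' @param snr_min Peak S/N threshold.
#' @param score_min Isotope similarity-score threshold.
#' @param blank_ratio_min Minimum sample/blank intensity ratio.
#' @param overlap CASI window overlap in Da.
#' @param windows CASI window bounds, see [casi_windows()].
#' @param ion Ion form name, see [ion_form()].
#' @param blank_filter Apply the blank filter when a blank is given.
#' @param fragment_filter Apply heteroatom-free fragment exclusion.
#' @return A `screen_config` list.
#' @export
screen_config <- function(tol_ppm = 1.5, k = 10, snr_min = 4, score_min = 75,
                          blank_ratio_min = 10, overlap = 5,
                          windows = casi_windows(), ion = "[M-H]-",
                          blank_filter = TRUE, fragment_filter = TRUE) {
  if (tol_ppm <= 0 || overlap < 0 || k < 1) {
    stop_schema("tolerances must be positive")
  }
  structure(list(tol_ppm = tol_ppm, k = k, snr_min = snr_min,
                 score_min = score_min, blank_ratio_min = blank_ratio_min,
                 overlap = overlap, windows = windows, ion = ion,
                 blank_filter = blank_filter,
                 fragment_filter = fragment_filter),
            class = "screen_config")
}

#' Run the full suspect screen
#'
#' Trims each CASI spectrum to its window with overlap, merges the windows,
#' optionally removes blank peaks, matches suspects within the ppm
#' tolerance, validates matches by isotopologue similarity, and reduces the
#' candidates in the fixed funnel order: duplicate removal, score threshold,
#' pKa/ionizability exclusion, fragment exclusion, composite ranking.
#'
#' @param suspects A `suspect_list` from [build_suspect_list()].
#' @param spectra A list of [spectrum()] objects (one per CASI window).
#' @param blank Optional blank peak list (spectrum or list of spectra).
#' @param config A [screen_config()].
#' @param formula_hook Optional offline formula-lookup hook, see
#'   [offline_formula_hook()].
#' @return A list with `candidates` (final ranked tibble), `funnel`
#'   (validated stage report), `matches` (all scored matches), `excluded`
#'   (per-stage removed tables), `peaks` (merged peak list) and `tables`
#'   (plot-ready tables from [export_plot_tables()]).
#' @export
pfas_screen <- function(suspects, spectra, blank = NULL,
                        config = screen_config(),
                        formula_hook = offline_formula_hook()) {
  trimmed <- lapply(if (inherits(spectra, "spectrum")) list(spectra) else
    spectra, trim_to_window, overlap = config$overlap)
  peaks <- merge_windows(trimmed)
  n_blank_flagged <- 0L
  if (!is.null(blank) && config$blank_filter) {
    blank_merged <- if (inherits(blank, "spectrum")) merge_windows(blank) else
      if (is.data.frame(blank)) blank else merge_windows(blank)
    bf <- blank_filter(peaks, blank_merged, ppm_tol = config$tol_ppm,
                       ratio_min = config$blank_ratio_min)
    n_blank_flagged <- nrow(bf$flagged)
    peaks <- bf$kept
  }
  matches <- match_suspects(peaks, suspects, k = config$k,
                            tol_ppm = config$tol_ppm)
  scored <- score_candidates(matches, suspects, peaks,
                             tol_ppm = config$tol_ppm)
  dd <- dedup_candidates(scored)
  st <- similarity_threshold(dd$kept, min_score = config$score_min)
  pk <- pka_exclusion(st$kept)
  fr <- if (config$fragment_filter) fragment_exclusion(pk$kept) else
    list(kept = pk$kept, removed = pk$kept[0, ])
  ranked <- composite_rank(fr$kept)
  funnel <- funnel_report(list(
    list(stage = "matched", n_in = nrow(scored), n_removed = 0L,
         n_out = nrow(scored), reason = "candidate annotations"),
    list(stage = "dedup", n_in = nrow(scored), n_removed = nrow(dd$removed),
         n_out = nrow(dd$kept), reason = "duplicate charged mass"),
    list(stage = "similarity", n_in = nrow(dd$kept),
         n_removed = nrow(st$removed), n_out = nrow(st$kept),
         reason = paste0("score < ", config$score_min)),
    list(stage = "pka_non_ionizable", n_in = nrow(st$kept),
         n_removed = nrow(pk$excluded_non_ionizable),
         n_out = nrow(st$kept) - nrow(pk$excluded_non_ionizable),
         reason = "no ionizable site"),
    list(stage = "pka_electropositive",
         n_in = nrow(st$kept) - nrow(pk$excluded_non_ionizable),
         n_removed = nrow(pk$excluded_electropositive),
         n_out = nrow(pk$kept), reason = "positive-mode only"),
    list(stage = "fragment", n_in = nrow(pk$kept),
         n_removed = nrow(fr$removed), n_out = nrow(fr$kept),
         reason = "(O+S+P+N)/C = 0")
  ))
  list(candidates = ranked, funnel = funnel, matches = scored,
       excluded = list(duplicates = dd$removed, low_score = st$removed,
                       non_ionizable = pk$excluded_non_ionizable,
                       electropositive = pk$excluded_electropositive,
                       fragments = fr$removed),
       peaks = peaks, n_blank_flagged = n_blank_flagged,
       tables = export_plot_tables(ranked),
       formula_hook = formula_hook)
}

#' Export plot-ready tables
#'
#' Kendrick mass defect, mass-defect distribution and elemental-ratio
#' tables for the final candidate list, on the measured m/z scale.
#'
#' @param candidates Ranked candidate table from [pfas_screen()] or
#'   [composite_rank()].
#' @param kendrick_base Repeat-unit formula for the Kendrick scale.
#' @return A list of tibbles `kmd`, `mass_defect`, `ratios`.
#' @export
export_plot_tables <- function(candidates, kendrick_base = "CF2") {
  if (nrow(candidates) == 0L) {
    return(list(
      kmd = tibble::tibble(suspect_id = character(), mz = numeric(),
                           kendrick_mass = numeric(), kmd = numeric()),
      mass_defect = tibble::tibble(suspect_id = character(), mz = numeric(),
                                   mass_defect = numeric()),
      ratios = tibble::tibble(suspect_id = character(), h_hal_c = numeric(),
                              ospn_c = numeric())))
  }
  km <- kendrick(candidates$measured_mz, base = kendrick_base)
  list(
    kmd = tibble::tibble(suspect_id = candidates$suspect_id, km),
    mass_defect = tibble::tibble(
      suspect_id = candidates$suspect_id, mz = candidates$measured_mz,
      mass_defect = candidates$measured_mz - round(candidates$measured_mz)),
    ratios = tibble::tibble(
      suspect_id = candidates$suspect_id,
      h_hal_c = candidates$h_hal_c, ospn_c = candidates$ospn_c,
      f_c = candidates$f_c, o_c = candidates$o_c,
      level = candidates$level, score = candidates$score)
  )
}

#' Plot candidate overview
#'
#' Renders the Kendrick mass defect plot or the elemental-ratio plot
#' ((H+halogens)/C against (O+S+P+N)/C) from the exported tables. Requires
#' ggplot2.
#'
#' @param tables Output of [export_plot_tables()].
#' @param which `"kmd"` or `"ratios"`.
#' @return A ggplot object.
#' @export
plot_candidates <- function(tables, which = c("kmd", "ratios")) {
  which <- match.arg(which)
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_schema("ggplot2 is required for plotting")
  }
  if (which == "kmd") {
    ggplot2::ggplot(tables$kmd,
                    ggplot2::aes(x = .data$kendrick_mass, y = .data$kmd)) +
      ggplot2::geom_point() +
      ggplot2::labs(x = "Kendrick mass (CF2)", y = "Kendrick mass defect")
  } else {
    ggplot2::ggplot(tables$ratios,
                    ggplot2::aes(x = .data$h_hal_c, y = .data$ospn_c)) +
      ggplot2::geom_point() +
      ggplot2::labs(x = "(H + halogens)/C", y = "(O + S + P + N)/C")
  }
}
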