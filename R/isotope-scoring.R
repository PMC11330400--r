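# Isotopologue pattern validation: predicted patterns anchored on the
# measured monoisotopic peak, weighted Euclidean similarity scoring on a
# 0-100 scale, and L-4/L-5 confidence levels.

#' Weighted Euclidean isotope score
#'
#' The scoring closed form. Per observation, the distance between the
#' measured and predicted isotopologue is
#' `d = sqrt(delta_ppm^2 + delta_rel_pct^2)` (mass deviation in ppm, signal
#' intensity as relative percentage difference, so the two axes are
#' commensurable) and the similarity is `1 / (1 + d)` in (0, 1]. Expected
#' but absent observations contribute similarity 0 with their weight
#' retained. Weights are the predicted intensities normalised to sum 1, so
#' high-intensity isotopologues dominate. The score is
#' `sum(similarity * weight) * 100`.
#'
#' @param delta_ppm,delta_rel_pct Numeric vectors of deviations; `NA` marks
#'   an expected-but-absent observation.
#' @param weights_raw Raw (unnormalised) weights, i.e. predicted intensities.
#' @return Score in `[0, 100]`.
#' @export
#' @examples
#' isotope_score(0, 0, 1)       # perfect pattern -> 100
#' isotope_score(3, 4, 1)       # d = 5 -> 100/6
isotope_score <- function(delta_ppm, delta_rel_pct, weights_raw) {
  if (length(weights_raw) == 0L || sum(weights_raw) <= 0) {
    stop_data("isotope_score needs positive weights")
  }
  d <- sqrt(delta_ppm^2 + delta_rel_pct^2)
  similarity <- ifelse(is.na(d), 0, 1 / (1 + d))
  w <- weights_raw / sum(weights_raw)
  sum(similarity * w) * 100
}

#' Predict the isotopologue pattern of a candidate
#'
#' Anchored on the measured monoisotopic peak: each isotopologue is
#' predicted at `measured_mz + mass_shift` with intensity
#' `measured_intensity * relative_abundance`. An isotopologue is *expected*
#' when its predicted intensity reaches the detection floor (the minimum
#' intensity retained in the peak's CASI window); sub-floor isotopologues
#' are excluded from scoring and the weights renormalise over the remainder.
#'
#' @param measured_mz,measured_intensity Monoisotopic peak as measured.
#' @param iso Isotopologue tibble from [isotopologues()] (columns `label`,
#'   `mass_shift`, `relative_abundance`).
#' @param floor Detection floor in intensity counts.
#' @return A tibble of unscored observations: `label`, `predicted_mz`,
#'   `predicted_intensity`, `expected`.
#' @export
predict_pattern <- function(measured_mz, measured_intensity, iso, floor) {
  if (measured_intensity <= 0) stop_data("monoisotopic intensity must be positive")
  if (is.null(iso) || nrow(iso) == 0L) {
    return(tibble::tibble(label = character(), predicted_mz = numeric(),
                          predicted_intensity = numeric(),
                          expected = logical()))
  }
  predicted <- measured_intensity * iso$relative_abundance
  tibble::tibble(
    label = iso$label,
    predicted_mz = measured_mz + iso$mass_shift,
    predicted_intensity = predicted,
    expected = predicted >= floor
  )
}

#' Score a predicted pattern against measured peaks
#'
#' For every expected observation the nearest peak within `tol_ppm` of the
#' predicted m/z is looked up (ties: smallest absolute ppm deviation, then
#' higher intensity). Any deviation from the simulated pattern reduces the
#' score; an expected isotopologue with no peak in tolerance scores
#' similarity 0 at full weight. Candidates with at least one expected
#' observation are level `"L4"` (scored); with none they are `"L5"`
#' (annotated by accurate mass only, no score).
#'
#' @param observations From [predict_pattern()].
#' @param peaks Peak table with `mz` and `intensity` (any window).
#' @param tol_ppm Lookup tolerance in ppm (default 1.5).
#' @return A list with `score` (0–100, or `NA` for L5), `level` and
#'   `observations` (input plus `measured_mz`, `measured_intensity`,
#'   `delta_ppm`, `delta_rel_pct`, `d`, `similarity`, `weight`).
#' @export
score_pattern <- function(observations, peaks, tol_ppm = 1.5) {
  obs <- observations
  n <- nrow(obs)
  obs$measured_mz <- rep(NA_real_, n)
  obs$measured_intensity <- rep(NA_real_, n)
  obs$delta_ppm <- rep(NA_real_, n)
  obs$delta_rel_pct <- rep(NA_real_, n)
  obs$d <- rep(NA_real_, n)
  obs$similarity <- rep(NA_real_, n)
  obs$weight <- rep(NA_real_, n)
  exp_idx <- which(obs$expected)
  if (!length(exp_idx)) {
    return(list(score = NA_real_, level = "L5", observations = obs))
  }
  mzs <- peaks$mz
  for (i in exp_idx) {
    pred <- obs$predicted_mz[i]
    dppm <- ppm_error(mzs, pred)
    inside <- which(abs(dppm) <= tol_ppm)
    if (!length(inside)) {
      obs$similarity[i] <- 0
      next
    }
    best <- inside[order(abs(dppm[inside]), -peaks$intensity[inside])][1L]
    obs$measured_mz[i] <- mzs[best]
    obs$measured_intensity[i] <- peaks$intensity[best]
    obs$delta_ppm[i] <- dppm[best]
    obs$delta_rel_pct[i] <-
      abs(peaks$intensity[best] - obs$predicted_intensity[i]) /
      obs$predicted_intensity[i] * 100
    obs$d[i] <- sqrt(obs$delta_ppm[i]^2 + obs$delta_rel_pct[i]^2)
    obs$similarity[i] <- 1 / (1 + obs$d[i])
  }
  w <- obs$predicted_intensity[exp_idx]
  obs$weight[exp_idx] <- w / sum(w)
  score <- sum(obs$similarity[exp_idx] * obs$weight[exp_idx]) * 100
  list(score = score, level = "L4", observations = obs)
}

#' Score all candidate annotations
#'
#' Runs [predict_pattern()] and [score_pattern()] for every candidate match,
#' using the per-window minimum retained intensity as detection floor.
#'
#' @param candidates Candidate table from [match_suspects()].
#' @param suspects The `suspect_list` the candidates came from.
#' @param peaks The merged peak list (isotopologue lookup space).
#' @param tol_ppm Lookup tolerance in ppm (default 1.5).
#' @param floor Optional global detection floor overriding the per-window
#'   minima.
#' @return `candidates` with columns `score`, `level` and a list-column
#'   `observations`.
#' @export
score_candidates <- function(candidates, suspects, peaks, tol_ppm = 1.5,
                             floor = NULL) {
  entries <- if (inherits(suspects, "suspect_list")) suspects$entries else
    suspects
  n <- nrow(candidates)
  score <- rep(NA_real_, n)
  level <- rep(NA_character_, n)
  obs_list <- vector("list", n)
  iso_by_id <- stats::setNames(entries$isotopologues, entries$id)
  for (i in seq_len(n)) {
    fl <- if (is.null(floor)) peak_floor(peaks, candidates$window[i]) else floor
    obs <- predict_pattern(candidates$measured_mz[i], candidates$intensity[i],
                           iso_by_id[[candidates$suspect_id[i]]], fl)
    res <- score_pattern(obs, peaks, tol_ppm)
    score[i] <- res$score
    level[i] <- res$level
    obs_list[[i]] <- res$observations
  }
  candidates$score <- score
  candidates$level <- level
  candidates$observations <- obs_list
  candidates
}
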