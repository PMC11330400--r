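# Candidate reduction: duplicate removal with S/N tie-break, similarity
# threshold, pKa/ionizability exclusion, heteroatom-free fragment exclusion,
# composite normalized ranking, and funnel bookkeeping.

#' Remove duplicate candidate annotations
#'
#' Duplicates arise from CASI window overlap (the same suspect matched in
#' two windows) and from salt/free-acid twins, which are recognised by their
#' identical charged mass. Per group of identical charged mass the candidate
#' whose mass peak has the highest S/N is retained (first occurrence on
#' ties).
#'
#' @param candidates Candidate table (with `theoretical_mz` and `snr`).
#' @return A list with `kept` and `removed` tables (a partition of the
#'   input).
#' @export
dedup_candidates <- function(candidates) {
  if (nrow(candidates) == 0L) {
    return(list(kept = candidates, removed = candidates))
  }
  key <- match(candidates$theoretical_mz, unique(candidates$theoretical_mz))
  keep <- logical(nrow(candidates))
  for (g in split(seq_along(key), key)) {
    keep[g[which.max(candidates$snr[g])]] <- TRUE
  }
  list(kept = candidates[keep, ], removed = candidates[!keep, ])
}

#' Similarity-score threshold
#'
#' Removes scored (L4) candidates below `min_score`. L5 candidates, which
#' carry no score, pass through: the funnel removes only scored candidates.
#'
#' @param candidates Scored candidate table.
#' @param min_score Minimum similarity score (default 75).
#' @return A list with `kept` and `removed`.
#' @export
similarity_threshold <- function(candidates, min_score = 75) {
  if (nrow(candidates) == 0L) {
    return(list(kept = candidates, removed = candidates))
  }
  drop <- candidates$level == "L4" & !is.na(candidates$score) &
    candidates$score < min_score
  list(kept = candidates[!drop, ], removed = candidates[drop, ])
}

#' pKa / ionizability exclusion
#'
#' Keeps candidates of class `acidic` (deprotonatable in negative ESI).
#' Exclusions are partitioned by reason for the funnel report:
#' `non_ionizable` molecules lack any ionizable site (e.g. perfluorohexane)
#' and `electropositive` ones carry only basic groups ionizable in positive
#' mode.
#'
#' @param candidates Candidate table with an `ionizability` column.
#' @return A list with `kept`, `excluded_non_ionizable` and
#'   `excluded_electropositive`.
#' @export
pka_exclusion <- function(candidates) {
  cls <- candidates$ionizability
  list(
    kept = candidates[cls == "acidic", ],
    excluded_non_ionizable = candidates[cls == "non_ionizable", ],
    excluded_electropositive = candidates[cls == "electropositive", ]
  )
}

#' Exclude likely in-source fragments
#'
#' Candidates with `(O + S + P + N)/C = 0` contain no heteroatoms besides
#' fluorine and likely originate from fragments of PFAS formed during
#' ionization; they are removed from further analysis.
#'
#' @param candidates Candidate table with an `ospn_c` column.
#' @return A list with `kept` and `removed`.
#' @export
fragment_exclusion <- function(candidates) {
  if (nrow(candidates) == 0L) {
    return(list(kept = candidates, removed = candidates))
  }
  drop <- !is.na(candidates$ospn_c) & candidates$ospn_c == 0
  list(kept = candidates[!drop, ], removed = candidates[drop, ])
}

# min-max normalisation mapping min -> 0, max -> 1; degenerate min == max
# (or a single candidate) maps to 0, the most desirable value
minmax01 <- function(x) {
  lo <- min(x, na.rm = TRUE)
  hi <- max(x, na.rm = TRUE)
  if (!is.finite(lo) || hi == lo) return(rep(0, length(x)))
  (x - lo) / (hi - lo)
}

#' Composite normalized ranking
#'
#' Ranks the final candidates by the unweighted mean of three normalized
#' variables, each on a 0 (best) to 1 (worst) scale: the absolute mass error
#' min–max normalized over the candidate set, the CompTox QC level mapped
#' linearly from 1 (highest confidence, 0) to 5 (lowest, 1), and the acidic
#' pKa min–max normalized so the most acidic candidate maps to 0. Sorted
#' ascending by composite with a stable tie-break on charged mass.
#'
#' @param candidates Candidate table with `ppm_error`, `qc_level`,
#'   `pka_acidic`.
#' @return The candidates with `norm_mass_acc`, `norm_qc`, `norm_pka`,
#'   `composite` and `rank` columns, sorted by rank.
#' @export
composite_rank <- function(candidates) {
  n <- nrow(candidates)
  if (n == 0L) {
    candidates$norm_mass_acc <- numeric(0)
    candidates$norm_qc <- numeric(0)
    candidates$norm_pka <- numeric(0)
    candidates$composite <- numeric(0)
    candidates$rank <- integer(0)
    return(candidates)
  }
  candidates$norm_mass_acc <- minmax01(abs(candidates$ppm_error))
  qc <- candidates$qc_level
  if (any(is.na(qc))) {
    warning("missing QC level; normalized to 1 (lowest confidence)",
            call. = FALSE)
    qc[is.na(qc)] <- 5L
  }
  candidates$norm_qc <- (qc - 1) / 4
  pka <- candidates$pka_acidic
  if (any(is.na(pka))) {
    warning("missing acidic pKa among ranked candidates; normalized to 1",
            call. = FALSE)
  }
  np <- minmax01(pka)
  np[is.na(pka)] <- 1
  candidates$norm_pka <- np
  candidates$composite <- (candidates$norm_mass_acc + candidates$norm_qc +
                             candidates$norm_pka) / 3
  ord <- order(candidates$composite, candidates$theoretical_mz)
  candidates <- candidates[ord, ]
  candidates$rank <- seq_len(n)
  candidates
}

#' Funnel report: stage-by-stage candidate bookkeeping
#'
#' Builds and validates the step-by-step reduction from matched candidates
#' to the final list. Every stage must conserve counts
#' (`n_in - n_removed = n_out`) and chain onto the next stage
#' (`n_out[i] = n_in[i+1]`); any inconsistency is an internal error.
#'
#' @param stages A list of stage entries, each a list/row with `stage`,
#'   `n_in`, `n_removed`, `n_out` and optionally `reason`.
#' @return A validated tibble with one row per stage.
#' @export
#' @examples
#' funnel_report(list(
#'   list(stage = "dedup", n_in = 238, n_removed = 48, n_out = 190),
#'   list(stage = "score", n_in = 190, n_removed = 7, n_out = 183)))
funnel_report <- function(stages) {
  rows <- lapply(stages, function(s) {
    tibble::tibble(stage = s$stage, n_in = as.integer(s$n_in),
                   n_removed = as.integer(s$n_removed),
                   n_out = as.integer(s$n_out),
                   reason = if (is.null(s$reason)) NA_character_ else s$reason)
  })
  out <- do.call(rbind, rows)
  bad <- out$n_in - out$n_removed != out$n_out
  if (any(bad)) {
    stop_internal("funnel stage '", out$stage[which(bad)[1L]],
                  "' does not conserve counts (n_in - n_removed != n_out)")
  }
  if (nrow(out) > 1L) {
    chain <- out$n_out[-nrow(out)] != out$n_in[-1L]
    if (any(chain)) {
      stop_internal("funnel stages '", out$stage[which(chain)[1L]], "' -> '",
                    out$stage[which(chain)[1L] + 1L], "' do not chain")
    }
  }
  out
}

#' Offline formula-lookup hook
#'
#' Interface point where an external molecular-formula service (such as a
#' PubChem query by m/z) can be plugged into the screen. The core contains
#' no network code; this stub returns an empty formula set for any query
#' and documents the expected signature `function(mz, tol_ppm)`.
#'
#' @return A function of `(mz, tol_ppm)` returning a tibble with a
#'   `formula` column.
#' @export
offline_formula_hook <- function() {
  function(mz, tol_ppm = 1.5) {
    tibble::tibble(mz = numeric(0), formula = character(0))
  }
}
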