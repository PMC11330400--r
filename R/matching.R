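# Distance-based suspect matching: nearest measured m/z neighbours per
# suspect charged mass, accepted within a ppm tolerance.

#' Signed mass error in ppm
#'
#' `(measured - theoretical) / theoretical * 1e6`.
#'
#' @param measured,theoretical Masses in Da; `theoretical > 0`. Vectorised.
#' @return Signed ppm error.
#' @export
#' @examples
#' ppm_error(349.98123, 349.98122)  # ~ +0.03 ppm
ppm_error <- function(measured, theoretical) {
  if (any(theoretical <= 0)) stop_data("theoretical mass must be positive")
  (measured - theoretical) / theoretical * 1e6
}

#' Match suspects against a measured peak list
#'
#' For each suspect, the `k` nearest measured m/z values (absolute Da
#' distance; in 1-D the Euclidean distance reduces to this) are paired with
#' the suspect's charged mass, and pairs with `|ppm_error| <= tol_ppm`
#' become candidate annotations. One measured peak may carry several suspect
#' annotations: suspects whose charged masses differ by less than the
#' tolerance (e.g. C11H6Cl2F6N2 and C6H2F12O3, 0.03 ppm apart) are both
#' retained as distinct annotations of the same signal. Ties at identical
#' distance are all kept.
#'
#' @param peaks A `merged_peaks` table (see [merge_windows()]).
#' @param suspects A `suspect_list` or its `entries` tibble.
#' @param k Neighbour count (default 10).
#' @param tol_ppm Mass tolerance in ppm (default 1.5).
#' @return A tibble of candidate matches: `suspect_id`, `formula`,
#'   `theoretical_mz`, `measured_mz`, `ppm_error`, `intensity`, `snr`,
#'   `window`, plus the suspect's QC/pKa/ionizability/descriptor columns.
#' @export
match_suspects <- function(peaks, suspects, k = 10, tol_ppm = 1.5) {
  if (tol_ppm <= 0 || k < 1) stop_schema("tol_ppm and k must be positive")
  entries <- if (inherits(suspects, "suspect_list")) suspects$entries else
    suspects
  empty <- tibble::tibble(
    suspect_id = character(), formula = character(),
    theoretical_mz = numeric(), measured_mz = numeric(),
    ppm_error = numeric(), intensity = numeric(), snr = numeric(),
    window = character())
  if (is.null(peaks) || nrow(peaks) == 0L || nrow(entries) == 0L) return(empty)
  ord <- order(peaks$mz)
  p <- peaks[ord, ]
  carry <- intersect(c("qc_level", "pka_acidic", "pka_basic", "ionizability",
                       "f_c", "h_c", "hf_c", "o_c", "h_hal_c", "ospn_c",
                       "dbe", "dbe_o", "n_elements", "n_atoms",
                       "mass_defect", "is_salt", "counterion"),
                     names(entries))
  out <- lapply(seq_len(nrow(entries)), function(i) {
    m <- entries$charged_mass[i]
    pos <- findInterval(m, p$mz)
    idx <- max(1L, pos - k):min(nrow(p), pos + k)
    d <- abs(p$mz[idx] - m)
    kth <- sort(d)[min(k, length(d))]
    idx <- idx[d <= kth]  # k nearest, ties kept
    ppm <- ppm_error(p$mz[idx], m)
    sel <- abs(ppm) <= tol_ppm
    if (!any(sel)) return(NULL)
    idx <- idx[sel]
    cbind(
      tibble::tibble(
        suspect_id = entries$id[i], formula = entries$formula[i],
        theoretical_mz = m, measured_mz = p$mz[idx],
        ppm_error = ppm[sel], intensity = p$intensity[idx],
        snr = p$snr[idx], window = p$window[idx]),
      entries[rep(i, sum(sel)), carry]
    )
  })
  out <- out[!vapply(out, is.null, logical(1L))]
  if (!length(out)) return(empty)
  tibble::as_tibble(do.call(rbind, out))
}
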