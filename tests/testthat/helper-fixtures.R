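# Fixtures are built in code; nothing is stored on disk.

# write a peak-list CSV in the m/z / intensity / S/N dialect
write_peak_csv <- function(df, path = tempfile(fileext = ".csv")) {
  names(df) <- c("m/z", "intensity", "S/N")[seq_along(df)]
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# write a raw suspect-list CSV with the required first column
write_raw_csv <- function(formulas, path = tempfile(fileext = ".csv"),
                          first_col = "Molecular formula", ...) {
  extra <- list(...)
  df <- data.frame(formulas, check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- first_col
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# brute-force all-pairs matching oracle: every (suspect, peak) pair within
# tol_ppm, capped at the k nearest peaks per suspect (ties kept)
brute_force_match <- function(mz, masses, k = 10, tol_ppm = 1.5) {
  out <- lapply(seq_along(masses), function(i) {
    d <- abs(mz - masses[i])
    kth <- sort(d)[min(k, length(d))]
    idx <- which(d <= kth)
    ppm <- (mz[idx] - masses[i]) / masses[i] * 1e6
    idx <- idx[abs(ppm) <= tol_ppm]
    if (!length(idx)) return(NULL)
    data.frame(suspect = i, peak = sort(idx))
  })
  do.call(rbind, out)
}

# independent straight-line implementation of the scoring closed forms
oracle_score <- function(delta_ppm, delta_rel_pct, predicted_intensity) {
  d <- sqrt(delta_ppm^2 + delta_rel_pct^2)
  sim <- 1 / (1 + d)
  sim[is.na(d)] <- 0
  W <- predicted_intensity / sum(predicted_intensity)
  sum(sim * W) * 100
}

# spike table mirroring the generator default (every non-salt suspect)
default_spikes_for_test <- function(sl, intensity = 1e6, ppm_offset = 0) {
  e <- sl$entries[!sl$entries$is_salt, ]
  tibble::tibble(id = e$id, intensity = intensity, ppm_offset = ppm_offset)
}

# a tiny merged peak list built directly from vectors
make_peaks <- function(mz, intensity = rep(1e6, length(mz)),
                       snr = rep(100, length(mz)),
                       window = rep("w", length(mz))) {
  s <- spectrum(tibble::tibble(mz = mz, intensity = intensity, snr = snr),
                window_lo = floor(min(mz)) - 10, window_hi = ceiling(max(mz)) + 10,
                label = window[1])
  merge_windows(list(s))
}
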