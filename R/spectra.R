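# Calibrated centroid peak lists: CSV reading with S/N thresholding, CASI
# window trimming with +/- 5 Da overlap, window merging with provenance, and
# blank filtering.

#' Default CASI window bounds
#'
#' The m/z segmentation used for spectral stitching on a 12 T FT-ICR
#' instrument: 150–230, 230–270, 270–300, then 100-Da windows up to 1000,
#' and 1000–2000 (11 windows).
#'
#' @return A tibble with columns `lo`, `hi`, `label`.
#' @export
casi_windows <- function() {
  lo <- c(150, 230, 270, seq(300, 900, by = 100), 1000)
  hi <- c(230, 270, 300, seq(400, 1000, by = 100), 2000)
  tibble::tibble(lo = lo, hi = hi, label = paste0(lo, "-", hi))
}

#' Construct a spectrum object
#'
#' A centroid peak list (m/z, intensity, S/N) tagged with its CASI window
#' bounds. Peaks are stored sorted ascending by m/z.
#'
#' @param peaks A data frame with columns `mz`, `intensity`, `snr`.
#' @param window_lo,window_hi CASI window bounds in Da (`lo < hi`).
#' @param label Window label.
#' @return A `spectrum` tibble with attributes `window_lo`, `window_hi`,
#'   `label`.
#' @export
spectrum <- function(peaks, window_lo, window_hi, label = NULL) {
  if (!is.null(window_lo) && !is.null(window_hi) && window_lo >= window_hi) {
    stop_data("window_lo must be smaller than window_hi")
  }
  peaks <- tibble::as_tibble(peaks)[c("mz", "intensity", "snr")]
  peaks <- peaks[order(peaks$mz), ]
  if (is.null(label)) label <- paste0(window_lo, "-", window_hi)
  structure(peaks, window_lo = window_lo, window_hi = window_hi,
            label = label,
            class = c("spectrum", class(peaks)))
}

#' Read a calibrated peak list from CSV
#'
#' Column names are configurable; rows with non-numeric or negative values
#' are collected as row errors (attribute `row_errors`), not fatal. Peaks
#' below the signal-to-noise threshold (default 4) are discarded; pass
#' `snr_min = NULL` to keep everything (required when no S/N column exists).
#'
#' @param path CSV file path.
#' @param window_lo,window_hi,label CASI window metadata (optional).
#' @param snr_min S/N threshold, or `NULL` to disable.
#' @param columns Named character vector mapping `mz`, `intensity`, `snr`
#'   to the CSV header names.
#' @return A [spectrum()] sorted by m/z.
#' @export
read_peaklist <- function(path, window_lo = NULL, window_hi = NULL,
                          label = NULL, snr_min = 4,
                          columns = c(mz = "m/z", intensity = "intensity",
                                      snr = "S/N")) {
  if (!file.exists(path)) stop_data("peak list file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop_data("empty peak list: ", path)
  for (key in c("mz", "intensity")) {
    if (!columns[[key]] %in% names(raw)) {
      stop_schema("peak list ", path, " lacks column '", columns[[key]], "'")
    }
  }
  has_snr <- columns[["snr"]] %in% names(raw)
  if (!has_snr && !is.null(snr_min)) {
    stop_schema("peak list ", path, " lacks column '", columns[["snr"]],
                "'; pass snr_min = NULL to read without an S/N threshold")
  }
  mz <- suppressWarnings(as.numeric(raw[[columns[["mz"]]]]))
  intensity <- suppressWarnings(as.numeric(raw[[columns[["intensity"]]]]))
  snr <- if (has_snr) {
    suppressWarnings(as.numeric(raw[[columns[["snr"]]]]))
  } else {
    rep(NA_real_, nrow(raw))
  }
  bad <- is.na(mz) | is.na(intensity) | mz <= 0 | intensity <= 0 |
    (has_snr & (is.na(snr) | snr < 0))
  row_errors <- tibble::tibble(row = which(bad),
                               reason = "non-numeric or non-positive value")
  keep <- !bad
  if (!is.null(snr_min)) keep <- keep & snr >= snr_min
  peaks <- tibble::tibble(mz = mz[keep], intensity = intensity[keep],
                          snr = snr[keep])
  if (nrow(peaks) == 0L) stop_data("no valid peaks in ", path)
  out <- spectrum(peaks, window_lo, window_hi, label)
  attr(out, "row_errors") <- row_errors
  out
}

#' Trim a spectrum to its CASI window with overlap
#'
#' Retains peaks with `window_lo - overlap <= mz <= window_hi + overlap`.
#' The ±5 Da default keeps isotopologues of species sitting at a window edge
#' (e.g. PFOS at 498.93022 Da in the 400–500 window, whose 18O isotopologue
#' at 500.93446 Da falls just beyond the bound); the duplicates this creates
#' across windows are removed later during candidate deduplication.
#'
#' @param s A [spectrum()] with window bounds set.
#' @param overlap Overlap in Da (default 5).
#' @return The trimmed spectrum.
#' @export
trim_to_window <- function(s, overlap = 5) {
  lo <- attr(s, "window_lo")
  hi <- attr(s, "window_hi")
  if (is.null(lo) || is.null(hi)) stop_data("spectrum has no window bounds")
  keep <- s$mz >= lo - overlap & s$mz <= hi + overlap
  out <- s[keep, ]
  attributes(out)[c("window_lo", "window_hi", "label")] <-
    attributes(s)[c("window_lo", "window_hi", "label")]
  class(out) <- class(s)
  out
}

#' Merge CASI window spectra into one peak list
#'
#' Concatenates spectra, tags every peak with its source window label
#' (provenance), and sorts by m/z with a stable order so duplicates arising
#' from window overlap stay adjacent and identifiable. The minimum retained
#' intensity per window is recorded (attribute `floors`) and later used as
#' the detection floor for isotope scoring.
#'
#' @param spectra A list of [spectrum()] objects (or a single spectrum).
#' @return A `merged_peaks` tibble with columns `mz`, `intensity`, `snr`,
#'   `window`, plus attribute `floors` (named vector, per-window minimum
#'   intensity).
#' @export
merge_windows <- function(spectra) {
  if (inherits(spectra, "spectrum")) spectra <- list(spectra)
  if (!length(spectra)) stop_data("no spectra to merge")
  parts <- lapply(spectra, function(s) {
    if (nrow(s) == 0L) return(NULL)
    tibble::tibble(mz = s$mz, intensity = s$intensity, snr = s$snr,
                   window = attr(s, "label"))
  })
  parts <- parts[!vapply(parts, is.null, logical(1L))]
  if (!length(parts)) stop_data("all spectra are empty")
  merged <- do.call(rbind, parts)
  merged <- merged[order(merged$mz), ]  # base order is stable
  floors <- tapply(merged$intensity, merged$window, min)
  structure(merged, floors = stats::setNames(as.numeric(floors),
                                             names(floors)),
            class = c("merged_peaks", class(merged)))
}

# per-peak detection floor, from the merged list's per-window minima
peak_floor <- function(peaks, window) {
  floors <- attr(peaks, "floors")
  if (is.null(floors)) return(min(peaks$intensity))
  out <- floors[window]
  out[is.na(out)] <- min(floors)
  unname(out)
}

#' Flag sample peaks also present in a blank measurement
#'
#' A sample peak is flagged when a blank peak lies within `ppm_tol` *and*
#' the sample/blank intensity ratio is below `ratio_min`. The return value
#' always partitions the sample: `kept` plus `flagged` reproduce the input
#' exactly. Whether flagged peaks are removed or only annotated is the
#' caller's choice.
#'
#' @param sample,blank `merged_peaks` (or spectrum) peak lists.
#' @param ppm_tol Mass tolerance in ppm (default 1.5, the global
#'   mass-accuracy setting).
#' @param ratio_min Minimum sample/blank intensity ratio to survive
#'   (default 10).
#' @return A list with `kept` and `flagged` peak tables.
#' @export
blank_filter <- function(sample, blank, ppm_tol = 1.5, ratio_min = 10) {
  if (ppm_tol <= 0) stop_schema("ppm_tol must be positive")
  if (ratio_min < 1) stop_schema("ratio_min must be >= 1")
  if (is.null(blank) || nrow(blank) == 0L) {
    return(list(kept = sample, flagged = sample[0, ]))
  }
  bmz <- sort(blank$mz)
  bint <- blank$intensity[order(blank$mz)]
  flagged <- vapply(seq_len(nrow(sample)), function(i) {
    mz <- sample$mz[i]
    tol <- mz * ppm_tol * 1e-6
    lo <- findInterval(mz - tol, bmz) + 1L
    hi <- findInterval(mz + tol, bmz)
    if (lo > hi) return(FALSE)
    any(sample$intensity[i] / bint[lo:hi] < ratio_min)
  }, logical(1L))
  keep_attrs <- attributes(sample)[c("floors")]
  kept <- sample[!flagged, ]
  flag <- sample[flagged, ]
  attr(kept, "floors") <- keep_attrs$floors
  class(kept) <- class(sample)
  list(kept = kept, flagged = flag)
}
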