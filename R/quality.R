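#' Default background exclusion windows
#'
#' Reproducible static background signals observed in sparse fragmentation
#' scans; peaks inside these windows are removed at every MS level. The
#' defaults ship as CSV (`inst/extdata/background_windows.csv`) and can be
#' extended with instrument-specific artifacts.
#'
#' @param path optional CSV with columns `center_mz`, `width` (full window
#'   width in Th).
#' @return data.frame of exclusion windows.
#' @export
default_background_windows <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "background_windows.csv",
                        package = "msnforest")
  }
  w <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("center_mz", "width") %in% names(w)), all(w$width > 0))
  w
}

#' Remove noise peaks from a scan
#'
#' Mass-detector style denoising: peaks with intensity below
#' `noise_factor * noise_floor` are removed, where the noise floor is the
#' scan's minimum raw peak intensity (fixed at scan construction, see
#' [msn_scan()]). With a factor > 1 the minimal peak itself is always
#' removed, and a scan whose peaks are all equal empties completely; such
#' spectra fail the minimum-signal filter anyway. Thresholding against the
#' stored floor makes the filter idempotent and lets it commute with
#' [remove_background()].
#'
#' @param scan an [msn_scan()].
#' @param noise_factor multiplier on the noise floor (default 2.5, applied
#'   at all MS levels).
#' @return the filtered scan (possibly with zero peaks).
#' @export
noise_filter <- function(scan, noise_factor = 2.5) {
  stopifnot(inherits(scan, "msn_scan"), noise_factor >= 0)
  threshold <- noise_factor * scan$noise_floor
  keep <- scan$intensity >= threshold
  replace_peaks(scan, scan$mz[keep], scan$intensity[keep])
}

#' Remove known background ions
#'
#' Removes peaks lying within any exclusion window
#' (`|mz - center_mz| <= width / 2`), at every MS level.
#'
#' @param scan an [msn_scan()].
#' @param windows exclusion window table ([default_background_windows()]).
#' @return the filtered scan.
#' @export
remove_background <- function(scan, windows = default_background_windows()) {
  stopifnot(inherits(scan, "msn_scan"))
  if (!nrow(windows) || !length(scan$mz)) return(scan)
  keep <- rep(TRUE, length(scan$mz))
  for (k in seq_len(nrow(windows))) {
    keep <- keep & abs(scan$mz - windows$center_mz[k]) > windows$width[k] / 2
  }
  replace_peaks(scan, scan$mz[keep], scan$intensity[keep])
}

# peak replacement preserving the scan's identity and stored noise floor
replace_peaks <- function(scan, mz, intensity) {
  scan$mz <- mz
  scan$intensity <- intensity
  scan$tic <- sum(intensity)
  scan
}

#' Precursor isolation purity from flanking MS1 scans
#'
#' Fraction (in percent) of the ion current inside the isolation window
#' that is attributable to the selected precursor, averaged over the
#' preceding and (when present) following MS1 scan. Attributable intensity
#' is the peak nearest the precursor m/z within `match_tol`, plus its
#' isotope peaks at `+k * 1.00335` Th (k = 1..`n_isotopes`, charge-1
#' spacing, same match tolerance). A window with no precursor peak scores 0
#' and is flagged chimeric.
#'
#' @param before preceding MS1 [msn_scan()].
#' @param after following MS1 scan, or `NULL` at the end of a file.
#' @param precursor_mz selected precursor m/z (Th).
#' @param isolation_width full isolation window width (Th).
#' @param match_tol peak match tolerance (Th).
#' @param n_isotopes isotope peaks attributed to the precursor.
#' @param chimeric_threshold purity (percent) below which the isolation is
#'   flagged chimeric.
#' @return list with `purity_pct`, `chimeric_flag`, `ms1_scans_used`.
#' @export
precursor_purity <- function(before, after = NULL, precursor_mz,
                             isolation_width = 1.2, match_tol = 0.01,
                             n_isotopes = 3L, chimeric_threshold = 90) {
  stopifnot(inherits(before, "msn_scan"), before$ms_level == 1L,
            precursor_mz > 0, isolation_width > 0)
  if (!is.null(after)) stopifnot(inherits(after, "msn_scan"),
                                 after$ms_level == 1L)
  scans <- if (is.null(after)) list(before) else list(before, after)
  purities <- vapply(scans, function(s) {
    single_scan_purity(s, precursor_mz, isolation_width, match_tol, n_isotopes)
  }, numeric(1L))
  purity <- mean(purities)
  list(purity_pct = purity,
       chimeric_flag = purity < chimeric_threshold,
       ms1_scans_used = length(scans))
}

single_scan_purity <- function(scan, precursor_mz, isolation_width,
                               match_tol, n_isotopes) {
  half <- isolation_width / 2
  inside <- which(abs(scan$mz - precursor_mz) <= half)
  if (!length(inside)) return(0)
  total <- sum(scan$intensity[inside])
  if (total <= 0) return(0)
  d <- abs(scan$mz[inside] - precursor_mz)
  if (min(d) > match_tol) return(0)
  main_idx <- inside[which.min(d)]
  attributable <- main_idx
  for (k in seq_len(n_isotopes)) {
    iso_mz <- scan$mz[main_idx] + k * 1.00335
    cand <- inside[abs(scan$mz[inside] - iso_mz) <= match_tol]
    attributable <- c(attributable, cand)
  }
  100 * sum(scan$intensity[unique(attributable)]) / total
}

#' Minimum-signal library filter
#'
#' A spectrum qualifies for library export only with at least `min_signals`
#' peaks surviving above the noise threshold.
#'
#' @param mz peak m/z vector (already noise-filtered), or an [msn_scan()].
#' @param min_signals minimum surviving peak count (default 2).
#' @return `TRUE` iff the spectrum qualifies.
#' @export
min_signal_filter <- function(mz, min_signals = 2L) {
  if (inherits(mz, "msn_scan")) mz <- mz$mz
  length(mz) >= min_signals
}
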