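# A "spectrum" throughout this file is a bare list(mz, intensity) with m/z
# ascending; library_entry and msn_scan objects are coerced on input.

as_spectrum <- function(x) {
  if (inherits(x, c("msn_scan", "library_entry"))) {
    return(list(mz = x$mz, intensity = x$intensity))
  }
  if (is.matrix(x)) return(list(mz = x[, 1L], intensity = x[, 2L]))
  stopifnot(is.list(x), !is.null(x$mz), !is.null(x$intensity))
  list(mz = as.numeric(x$mz), intensity = as.numeric(x$intensity))
}

normalize_base_peak <- function(sp, to = 100) {
  if (!length(sp$intensity)) return(sp)
  m <- max(sp$intensity)
  if (m > 0) sp$intensity <- sp$intensity / m * to
  sp
}

#' Bin peaks across spectra into a merged spectrum
#'
#' The merging primitive behind all consensus levels. Each source spectrum
#' is base-peak-normalized to 100, all peaks are pooled and grouped greedily
#' in ascending m/z (single linkage; a gap larger than `mz_tol` starts a new
#' group). Each merged peak takes the intensity-weighted mean m/z of its
#' members and, by default, the maximum of the normalized member
#' intensities — a fragment prominent at any single energy stays prominent
#' in the merge. The result is independent of the order in which spectra
#' are supplied.
#'
#' @param spectra list of spectra (`list(mz, intensity)`, [msn_scan()] or
#'   [library_entry()] objects).
#' @param mz_tol binning tolerance in Th (default 0.005, the spectral
#'   matching tolerance).
#' @param aggregate intensity aggregation across members: `"max"`
#'   (default), `"sum"` or `"mean"`.
#' @return merged spectrum `list(mz, intensity)`, m/z ascending, intensity
#'   on the base-peak-100 scale (`"max"`/`"mean"`; `"sum"` can exceed 100).
#' @export
bin_peaks <- function(spectra, mz_tol = 0.005,
                      aggregate = c("max", "sum", "mean")) {
  aggregate <- match.arg(aggregate)
  spectra <- lapply(spectra, function(s) normalize_base_peak(as_spectrum(s)))
  mz <- unlist(lapply(spectra, `[[`, "mz"), use.names = FALSE)
  int <- unlist(lapply(spectra, `[[`, "intensity"), use.names = FALSE)
  if (!length(mz)) return(list(mz = numeric(0), intensity = numeric(0)))
  grp <- cluster_by_tol(mz, mz_tol)
  agg_fun <- switch(aggregate, max = max, sum = sum, mean = mean)
  merged_mz <- vapply(split(seq_along(mz), grp), function(ix) {
    if (length(ix) == 1L) return(mz[ix])
    w <- int[ix]
    if (sum(w) > 0) sum(mz[ix] * w) / sum(w) else mean(mz[ix])
  }, numeric(1L))
  merged_int <- vapply(split(int, grp), agg_fun, numeric(1L))
  ord <- order(merged_mz)
  list(mz = as.numeric(merged_mz[ord]), intensity = as.numeric(merged_int[ord]))
}

#' Same-energy consensus spectrum of a tree node
#'
#' Consensus over the repeat-trigger scans a node holds at one collision
#' energy. Requires at least two scans at that energy; with fewer the
#' caller falls back to the single best scan.
#'
#' @param node an [msn_tree] node.
#' @param energy collision energy in eV.
#' @param mz_tol binning tolerance in Th.
#' @return merged spectrum with attributes `energies` and `scan_numbers`,
#'   or `NULL` when fewer than two scans exist at `energy`.
#' @export
merge_same_energy <- function(node, energy, mz_tol = 0.005) {
  stopifnot(inherits(node, "msn_tree"))
  at_energy <- Filter(function(s) {
    e <- scan_energy(s)
    !is.na(e) && abs(e - energy) <= 1e-9
  }, node$scans)
  if (length(at_energy) < 2L) return(NULL)
  sp <- bin_peaks(at_energy, mz_tol = mz_tol)
  attr(sp, "energies") <- energy
  attr(sp, "scan_numbers") <- sort(vapply(at_energy, `[[`, integer(1L),
                                          "scan_number"))
  sp
}

#' Merged spectrum across all collision energies of a node
#'
#' For each energy present at the node, the same-energy consensus is used
#' when available (two or more repeat triggers), otherwise the best single
#' scan; those per-energy spectra are then binned into one spectrum.
#'
#' @inheritParams merge_same_energy
#' @return merged spectrum with attributes `energies` (all distinct
#'   energies used) and `scan_numbers`, or `NULL` for a node without usable
#'   scans.
#' @export
merge_all_energies <- function(node, mz_tol = 0.005) {
  stopifnot(inherits(node, "msn_tree"))
  energies <- node_energies(node)
  energies <- energies[!is.na(energies)]
  if (!length(energies)) return(NULL)
  parts <- list(); scan_numbers <- integer(0)
  for (e in energies) {
    sp <- merge_same_energy(node, e, mz_tol = mz_tol)
    if (is.null(sp)) {
      best <- select_best_scan(node, e)
      if (is.null(best)) next
      sp <- as_spectrum(best)
      attr(sp, "scan_numbers") <- best$scan_number
    }
    parts[[length(parts) + 1L]] <- sp
    scan_numbers <- c(scan_numbers, attr(sp, "scan_numbers"))
  }
  if (!length(parts)) return(NULL)
  merged <- bin_peaks(parts, mz_tol = mz_tol)
  attr(merged, "energies") <- energies
  attr(merged, "scan_numbers") <- sort(unique(scan_numbers))
  merged
}

#' Collapse a full MSn tree into a pseudo-MS2 spectrum
#'
#' Unions the all-energies spectra of every node in the subtree (root and
#' all descendants) into one MS2-like composite. Each node's residual
#' precursor signal is trimmed (peaks at and above the node's own precursor
#' m/z) before the union, so the composite is a pure fragment spectrum.
#' Intensities are not re-weighted by level.
#'
#' @param root an annotated MS2-level [msn_tree] node.
#' @param mz_tol binning tolerance in Th.
#' @param precursor_trim_tol tolerance of the per-stage precursor trim.
#' @return merged spectrum with attributes `energies` and `scan_numbers`
#'   (may have zero peaks for a degenerate tree).
#' @export
build_pseudo_ms2 <- function(root, mz_tol = 0.005, precursor_trim_tol = 0.005) {
  stopifnot(inherits(root, "msn_tree"), root$ms_level == 2L)
  nodes <- tree_nodes(root)
  parts <- list(); energies <- numeric(0); scan_numbers <- integer(0)
  for (node in nodes) {
    sp <- merge_all_energies(node, mz_tol = mz_tol)
    if (is.null(sp)) next
    sp <- remove_precursor_peaks(sp, node$precursor_mz, tol = precursor_trim_tol)
    if (!length(sp$mz)) next
    parts[[length(parts) + 1L]] <- sp
    energies <- c(energies, attr(sp, "energies"))
    scan_numbers <- c(scan_numbers, attr(sp, "scan_numbers"))
  }
  merged <- bin_peaks(parts, mz_tol = mz_tol)
  attr(merged, "energies") <- sort(unique(energies))
  attr(merged, "scan_numbers") <- sort(unique(scan_numbers))
  merged
}
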