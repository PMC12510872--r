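#' Remove precursor signals from a spectrum
#'
#' Default behavior drops every peak at or above `precursor_mz - tol` —
#' the standard cosine-preparation step, which also removes isotope and
#' multimer residues riding above the precursor. `mode = "window"` removes
#' only the `precursor_mz +/- tol` window.
#'
#' @param spectrum `list(mz, intensity)`, [msn_scan()] or [library_entry()].
#' @param precursor_mz precursor m/z in Th.
#' @param tol tolerance in Th.
#' @param mode `"above"` (default) or `"window"`.
#' @return the trimmed spectrum (`list(mz, intensity)`; other attributes
#'   preserved).
#' @export
remove_precursor_peaks <- function(spectrum, precursor_mz, tol = 0.005,
                                   mode = c("above", "window")) {
  mode <- match.arg(mode)
  sp <- as_spectrum(spectrum)
  keep <- if (mode == "above") {
    sp$mz < precursor_mz - tol
  } else {
    abs(sp$mz - precursor_mz) > tol
  }
  out <- list(mz = sp$mz[keep], intensity = sp$intensity[keep])
  extra <- setdiff(names(attributes(spectrum)), c("names", "class"))
  for (a in extra) attr(out, a) <- attr(spectrum, a)
  out
}

# greedy one-to-one peak pairing within mz_tol: candidate pairs ordered by
# ascending |delta m/z|, ties to the larger intensity product, each peak
# used at most once
pair_peaks_greedy <- function(a, b, mz_tol) {
  na <- length(a$mz); nb <- length(b$mz)
  if (!na || !nb) return(cbind(i = integer(0), j = integer(0)))
  cand_i <- integer(0); cand_j <- integer(0)
  for (i in seq_len(na)) {
    js <- which(abs(b$mz - a$mz[i]) <= mz_tol)
    cand_i <- c(cand_i, rep(i, length(js)))
    cand_j <- c(cand_j, js)
  }
  if (!length(cand_i)) return(cbind(i = integer(0), j = integer(0)))
  d <- abs(a$mz[cand_i] - b$mz[cand_j])
  prod <- a$intensity[cand_i] * b$intensity[cand_j]
  ord <- order(d, -prod, cand_i, cand_j)
  used_a <- logical(na); used_b <- logical(nb)
  keep_i <- integer(0); keep_j <- integer(0)
  for (k in ord) {
    i <- cand_i[k]; j <- cand_j[k]
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    keep_i <- c(keep_i, i); keep_j <- c(keep_j, j)
  }
  cbind(i = keep_i, j = keep_j)
}

#' Weighted cosine similarity of two spectra
#'
#' Cosine similarity on weighted peak vectors with
#' `w = mz^mz_power * intensity^intensity_power` (default: square-root
#' intensity weighting, `mz^0 * I^0.5`). Peaks are paired one-to-one by
#' greedy best m/z agreement within `mz_tol`; the score is
#' `(sum w_a w_b)^2 / (sum w_a^2 * sum w_b^2)` over all peaks of each
#' spectrum, so unmatched peaks penalize through the norms. Symmetric and
#' invariant to uniform intensity scaling of either spectrum.
#'
#' @param a,b spectra (`list(mz, intensity)`, [msn_scan()] or
#'   [library_entry()]), non-empty.
#' @param mz_tol peak match tolerance in Th.
#' @param mz_power,intensity_power weighting exponents.
#' @return list with `score` in `[0, 1]` and `matched_signals`.
#' @export
weighted_cosine <- function(a, b, mz_tol = 0.005, mz_power = 0,
                            intensity_power = 0.5) {
  a <- as_spectrum(a); b <- as_spectrum(b)
  if (!length(a$mz) || !length(b$mz)) {
    stop("weighted_cosine requires non-empty spectra")
  }
  wa <- a$mz^mz_power * a$intensity^intensity_power
  wb <- b$mz^mz_power * b$intensity^intensity_power
  pairs <- pair_peaks_greedy(a, b, mz_tol)
  dot <- sum(wa[pairs[, "i"]] * wb[pairs[, "j"]])
  denom <- sum(wa^2) * sum(wb^2)
  score <- if (denom > 0) dot^2 / denom else 0
  list(score = min(score, 1), matched_signals = nrow(pairs))
}

#' Search query spectra against a spectral library
#'
#' Candidate pairs are restricted by precursor m/z agreement within
#' `max(precursor_tol_abs, precursor_tol_ppm)`; precursor signals are
#' removed from both sides; pairs are scored with [weighted_cosine()] and
#' kept with `score >= min_score` and `matched_signals >= min_matched`,
#' ranked by score and truncated to `top_k` per query.
#'
#' @param queries,library lists of [library_entry()] objects.
#' @param precursor_tol_abs,precursor_tol_ppm precursor matching tolerance.
#' @param mz_tol fragment match tolerance in Th.
#' @param min_score minimum similarity retained.
#' @param min_matched minimum matched signal count retained.
#' @param top_k matches reported per query (`Inf` for all).
#' @param dedupe_by_compound when `TRUE`, only the best-scoring hit per
#'   library compound (InChIKey, falling back to name) enters the ranking.
#' @param ... passed to [weighted_cosine()].
#' @return data.frame of match results: `query_id`, `library_id`, `score`,
#'   `matched_signals`, `precursor_delta_mz`.
#' @export
library_search <- function(queries, library,
                           precursor_tol_abs = 0.005, precursor_tol_ppm = 10,
                           mz_tol = 0.005, min_score = 0.6, min_matched = 4L,
                           top_k = Inf, dedupe_by_compound = FALSE, ...) {
  lib_pmz <- vapply(library, `[[`, numeric(1L), "precursor_mz")
  lib_id <- entry_ids(library)
  lib_compound <- vapply(library, function(e) {
    if (!is.na(e$inchikey)) e$inchikey else e$name
  }, character(1L))
  out <- list()
  qids <- entry_ids(queries)
  for (qi in seq_along(queries)) {
    q <- queries[[qi]]
    tol <- max(precursor_tol_abs, precursor_tol_ppm * q$precursor_mz * 1e-6)
    cand <- which(abs(lib_pmz - q$precursor_mz) <= tol)
    if (!length(cand)) next
    qsp <- remove_precursor_peaks(q, q$precursor_mz)
    if (!length(qsp$mz)) next
    rows <- list()
    for (li in cand) {
      lsp <- remove_precursor_peaks(library[[li]], lib_pmz[li])
      if (!length(lsp$mz)) next
      wc <- weighted_cosine(qsp, lsp, mz_tol = mz_tol, ...)
      if (wc$score >= min_score && wc$matched_signals >= min_matched) {
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = qids[qi], library_id = lib_id[li],
          compound = lib_compound[li],
          score = wc$score, matched_signals = wc$matched_signals,
          precursor_delta_mz = lib_pmz[li] - q$precursor_mz,
          stringsAsFactors = FALSE)
      }
    }
    if (!length(rows)) next
    hits <- do.call(rbind, rows)
    hits <- hits[order(-hits$score, abs(hits$precursor_delta_mz)), , drop = FALSE]
    if (dedupe_by_compound) {
      hits <- hits[!duplicated(hits$compound), , drop = FALSE]
    }
    if (is.finite(top_k)) hits <- utils::head(hits, top_k)
    out[[length(out) + 1L]] <- hits
  }
  if (!length(out)) {
    return(data.frame(query_id = character(0), library_id = character(0),
                      compound = character(0), score = numeric(0),
                      matched_signals = integer(0),
                      precursor_delta_mz = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

entry_ids <- function(entries) {
  vapply(seq_along(entries), function(i) {
    e <- entries[[i]]
    nm <- if (!is.na(e$name) && nzchar(e$name)) e$name else "entry"
    sprintf("%s#%d", nm, i)
  }, character(1L))
}

#' Library overlap by InChIKey connectivity block
#'
#' Reduces each source's InChIKeys to the first 14-character connectivity
#' block (stereochemistry removed) and counts, UpSet-style, the blocks
#' falling in every non-empty source-membership pattern.
#'
#' @param sources named list: source name -> character vector of
#'   27-character InChIKeys or bare 14-character first blocks.
#' @return list with `pattern_counts` (named by `"A&B"`-style membership
#'   patterns), `per_source_unique`, `union_size` and `membership` (the
#'   per-block pattern table).
#' @export
overlap_sets <- function(sources) {
  stopifnot(is.list(sources), length(sources) > 0,
            !is.null(names(sources)), all(nzchar(names(sources))))
  blocks <- lapply(names(sources), function(nm) {
    keys <- as.character(sources[[nm]])
    full <- grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", keys)
    bare <- grepl("^[A-Z]{14}$", keys)
    bad <- which(!full & !bare)
    if (length(bad)) {
      stop("malformed InChIKey in source '", nm, "': ", keys[bad[1L]])
    }
    unique(substr(keys, 1L, 14L))
  })
  names(blocks) <- names(sources)
  all_blocks <- sort(unique(unlist(blocks, use.names = FALSE)))
  member <- vapply(blocks, function(b) all_blocks %in% b,
                   logical(length(all_blocks)))
  member <- matrix(member, nrow = length(all_blocks),
                   dimnames = list(all_blocks, names(sources)))
  pattern <- apply(member, 1L, function(row) {
    paste(names(sources)[row], collapse = "&")
  })
  counts <- table(pattern)
  uniques <- vapply(names(sources), function(nm) {
    sum(pattern == nm)
  }, integer(1L))
  list(pattern_counts = stats::setNames(as.integer(counts), names(counts)),
       per_source_unique = uniques,
       union_size = length(all_blocks),
       membership = data.frame(block = all_blocks, pattern = unname(pattern),
                               stringsAsFactors = FALSE))
}

#' Tanimoto structure similarity
#'
#' Tanimoto coefficient on circular (extended-connectivity, radius 2)
#' fingerprints folded to 2048 bits.
#'
#' @param a,b structure strings (SMILES, or InChI detected by prefix).
#' @return similarity in `[0, 1]`.
#' @export
tanimoto_similarity <- function(a, b) {
  fa <- structure_fingerprint(a)
  fb <- structure_fingerprint(b)
  denom <- sum(fa | fb)
  if (denom == 0) return(0)
  sum(fa & fb) / denom
}

structure_fingerprint <- function(x, nbits = 2048L) {
  stopifnot(is.character(x), length(x) == 1L, nzchar(x))
  smi <- if (startsWith(x, "InChI=")) ob_convert(x, from = "inchi", to = "can") else x
  if (is.na(smi)) stop("cannot parse structure: ", x)
  ob_morgan_fp(smi, nbits = nbits)
}
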