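#' Default adduct and in-source fragment table
#'
#' The ion species tested during annotation. `mass_delta` is the signed mass
#' added to `multimer * M` before division by `|charge|`, and includes the
#' electron-mass correction (so the proton delta is 1.007276 Da, not the H
#' atom mass): at 10 ppm tolerances below m/z 200 the electron mass is
#' larger than the matching window. The set is configuration: edit the
#' shipped CSV (`system.file("extdata", "adducts.csv", package =
#' "msnforest")`) or pass your own table.
#'
#' @param path optional CSV with columns `name`, `multimer`, `mass_delta`,
#'   `charge`, `polarity`.
#' @return data.frame of adduct definitions.
#' @export
default_adducts <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "adducts.csv", package = "msnforest")
  }
  adducts <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("name", "multimer", "mass_delta", "charge", "polarity")
  if (!all(needed %in% names(adducts))) {
    stop("adduct table must have columns: ", paste(needed, collapse = ", "))
  }
  bad <- sign(adducts$charge) != ifelse(adducts$polarity == "positive", 1, -1)
  if (any(adducts$charge == 0) || any(bad)) {
    stop("adduct charge sign must be non-zero and consistent with polarity")
  }
  adducts
}

#' Expected ion m/z for an adduct of a neutral molecule
#'
#' `(multimer * M + mass_delta) / |charge|`, the exact m/z at which an
#' adduct or in-source fragment ion of a compound with monoisotopic mass `M`
#' is expected.
#'
#' @param monoisotopic_mass neutral monoisotopic mass M in Da (> 0).
#' @param adduct one row of an adduct table (list or data.frame row with
#'   `multimer`, `mass_delta`, `charge`).
#' @return expected m/z in Th.
#' @examples
#' h <- list(name = "[M+H]+", multimer = 1, mass_delta = 1.007276466,
#'           charge = 1, polarity = "positive")
#' expected_ion_mz(180.0634, h)  # 181.0707
#' @export
expected_ion_mz <- function(monoisotopic_mass, adduct) {
  stopifnot(all(monoisotopic_mass > 0))
  (adduct$multimer * monoisotopic_mass + adduct$mass_delta) / abs(adduct$charge)
}

#' Compounds expected in a scan file
#'
#' Resolves which curated compounds were injected in the sample a scan file
#' came from, by locating a unique sample identifier as a delimiter-guarded
#' substring of the file name. The identifier must be bounded by
#' non-alphanumeric characters (or the string edges), so `"P1_A1"` cannot
#' fire inside `"P1_A11"`.
#'
#' @param filename scan file name (path components are ignored).
#' @param metadata curated compound table with `unique_sample_id`.
#' @return the metadata rows of the matched well (zero rows, with a warning,
#'   when no identifier matches). A file name matching more than one
#'   distinct identifier is an error: names must be unambiguous.
#' @export
compounds_for_file <- function(filename, metadata) {
  stopifnot(is.data.frame(metadata), "unique_sample_id" %in% names(metadata))
  fname <- basename(filename)
  ids <- unique(metadata$unique_sample_id)
  hit <- vapply(ids, function(id) {
    pat <- paste0("(?<![A-Za-z0-9])", gsub("([^A-Za-z0-9])", "\\\\\\1", id),
                  "(?![A-Za-z0-9])")
    grepl(pat, fname, perl = TRUE)
  }, logical(1L))
  matched <- ids[hit]
  if (length(matched) > 1L) {
    stop("file name '", fname, "' matches multiple sample identifiers: ",
         paste(matched, collapse = ", "))
  }
  if (!length(matched)) {
    warning("no sample identifier found in file name '", fname, "'")
    return(metadata[integer(0), , drop = FALSE])
  }
  metadata[metadata$unique_sample_id == matched, , drop = FALSE]
}

#' Annotate tree roots against the compounds known to be in the sample
#'
#' For each MS2 root of the forest, tests every (candidate compound,
#' polarity-matching adduct) pair and keeps those whose expected ion m/z
#' agrees with the root's observed precursor m/z within
#' `max(tol_abs, tol_ppm * expected * 1e-6)`. All matches are retained and
#' ranked by absolute ppm error per root; isomeric candidates therefore
#' yield multiple annotations on one root, flagged ambiguous.
#'
#' @param forest list of [msn_tree()] roots from one scan file.
#' @param candidates compound rows from [compounds_for_file()] (must carry
#'   `monoisotopic_mass`).
#' @param adducts adduct table ([default_adducts()]).
#' @param polarity polarity of the file's scans.
#' @param tol_ppm,tol_abs matching tolerance (combined as the more
#'   permissive of the two).
#' @return data.frame with one row per (root, compound, adduct) match:
#'   `root`, `observed_mz`, `expected_mz`, `mz_error_ppm`, `adduct_name`,
#'   `ambiguous`, plus the candidate's metadata columns.
#' @export
annotate_forest <- function(forest, candidates, adducts = default_adducts(),
                            polarity = "positive",
                            tol_ppm = 10, tol_abs = 0.005) {
  adducts <- adducts[adducts$polarity == polarity, , drop = FALSE]
  out <- list()
  if (nrow(candidates) && nrow(adducts)) {
    for (ri in seq_along(forest)) {
      root <- forest[[ri]]
      if (root$ms_level != 2L) next
      obs <- root$precursor_mz
      for (ci in seq_len(nrow(candidates))) {
        M <- candidates$monoisotopic_mass[ci]
        if (is.na(M)) next
        exp_mz <- expected_ion_mz(M, adducts)
        tol <- pmax(tol_abs, tol_ppm * exp_mz * 1e-6)
        ok <- which(abs(obs - exp_mz) <= tol)
        for (ai in ok) {
          err_ppm <- (obs - exp_mz[ai]) / exp_mz[ai] * 1e6
          out[[length(out) + 1L]] <- cbind(
            data.frame(root = ri, observed_mz = obs,
                       expected_mz = exp_mz[ai],
                       mz_error_ppm = err_ppm,
                       adduct_name = adducts$name[ai],
                       stringsAsFactors = FALSE),
            candidates[ci, , drop = FALSE])
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(root = integer(0), observed_mz = numeric(0),
                      expected_mz = numeric(0), mz_error_ppm = numeric(0),
                      adduct_name = character(0), ambiguous = logical(0)))
  }
  ann <- do.call(rbind, out)
  rownames(ann) <- NULL
  ann <- ann[order(ann$root, abs(ann$mz_error_ppm)), , drop = FALSE]
  ann$ambiguous <- stats::ave(seq_len(nrow(ann)), ann$root,
                              FUN = length) > 1L
  rownames(ann) <- NULL
  ann
}
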