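#' Assign unique sample identifiers
#'
#' Builds the deterministic per-well sample identifier
#' `LIBRARY_PLATE_WELL` (upper-cased, `"_"`-delimited). All compounds pooled
#' in the same well share one identifier; wells differing in library, plate
#' or well position get distinct identifiers by construction. The identifier
#' is later matched as a delimiter-guarded substring of acquisition file
#' names, which is what ties scan files back to their known compounds.
#'
#' @param records data.frame with `library_code`, `plate` and `well` columns.
#' @return `records` with a `unique_sample_id` column added (or replaced).
#' @export
assign_sample_ids <- function(records) {
  stopifnot(is.data.frame(records))
  for (col in c("library_code", "plate", "well")) {
    if (!col %in% names(records)) stop("records lack column '", col, "'")
  }
  lib <- trimws(as.character(records$library_code))
  plate <- trimws(as.character(records$plate))
  well <- trimws(as.character(records$well))
  bad <- which(is.na(lib) | !nzchar(lib) | is.na(plate) | !nzchar(plate) |
                 is.na(well) | !nzchar(well))
  if (length(bad)) {
    stop("missing library/plate/well in row(s): ", paste(bad, collapse = ", "))
  }
  records$unique_sample_id <- toupper(paste(lib, plate, well, sep = "_"))
  records
}

#' Duplicate analysis of curated structures
#'
#' Groups compounds by InChIKey, either the full 27-character key
#' (stereochemistry-aware) or only its first 14-character connectivity
#' block (stereochemistry removed), and reports total and unique counts.
#'
#' @param inchikeys character vector of InChIKeys, or a data.frame with an
#'   `inchikey` column.
#' @param stereo if `TRUE` group by the full key; if `FALSE` by the first
#'   block only.
#' @return list with `total_count`, `unique_count`, and `groups`: a
#'   data.frame mapping each input `inchikey` to its `group_key` and the
#'   representative (first) input index of the group.
#' @export
dedupe_structures <- function(inchikeys, stereo = TRUE) {
  if (is.data.frame(inchikeys)) inchikeys <- inchikeys$inchikey
  inchikeys <- as.character(inchikeys)
  if (any(!is_valid_inchikey(inchikeys))) {
    bad <- inchikeys[!is_valid_inchikey(inchikeys)]
    stop("malformed InChIKey(s): ", paste(utils::head(bad, 5L), collapse = ", "))
  }
  key <- if (stereo) inchikeys else substr(inchikeys, 1L, 14L)
  rep_idx <- stats::ave(seq_along(key), key, FUN = function(i) i[1L])
  list(
    total_count = length(key),
    unique_count = length(unique(key)),
    groups = data.frame(inchikey = inchikeys, group_key = key,
                        representative = as.integer(rep_idx),
                        stringsAsFactors = FALSE)
  )
}

#' Detected-compound coverage
#'
#' Percentage of sourced unique structures for which library spectra were
#' generated.
#'
#' @param n_detected number of detected unique compounds.
#' @param n_sourced number of sourced unique structures.
#' @return coverage in percent.
#' @export
coverage_pct <- function(n_detected, n_sourced) {
  stopifnot(n_sourced > 0, n_detected >= 0)
  100 * n_detected / n_sourced
}
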