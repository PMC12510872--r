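#' Generate a flow-injection acquisition sequence
#'
#' Builds the injection sequence for a set of plates: within each plate all
#' wells are first acquired in positive ion mode, then all wells in negative
#' ion mode. File names are assembled as
#' `<date>_<unique_sample_id>_<method>_<polarity>`, so every file name
#' contains its well's sample identifier as a delimiter-bounded substring
#' and annotation can later recover the well from the name alone.
#'
#' @param wells data.frame with one row per well, carrying
#'   `library_code`, `plate`, `well` (and optionally `unique_sample_id`;
#'   it is rebuilt if absent). A well recurring within a plate is an
#'   error; collapse a compound table to unique wells first (see
#'   [unique_wells()]).
#' @param start_date acquisition date (`Date` or `"YYYY-MM-DD"` string).
#' @param method_name acquisition method label used in file names.
#' @param path optional CSV output path.
#' @return data.frame of sequence rows: `acquisition_date`,
#'   `unique_sample_id`, `method_name`, `polarity`, `filename`,
#'   `injection_index`.
#' @export
generate_sequence <- function(wells, start_date, method_name, path = NULL) {
  stopifnot(is.data.frame(wells), nrow(wells) > 0)
  if (!"unique_sample_id" %in% names(wells)) wells <- assign_sample_ids(wells)
  date <- as.Date(start_date)
  if (is.na(date)) stop("start_date is not a valid date")

  dup <- duplicated(wells$unique_sample_id)
  if (any(dup)) {
    stop("duplicate well(s) within a plate: ",
         paste(unique(wells$unique_sample_id[dup]), collapse = ", "),
         " (collapse compound tables to unique wells first)")
  }
  plate_key <- paste(wells$library_code, wells$plate, sep = "_")

  rows <- list()
  for (pk in unique(plate_key)) {
    pw <- wells[plate_key == pk, , drop = FALSE]
    for (pol in c("positive", "negative")) {
      rows[[length(rows) + 1L]] <- data.frame(
        acquisition_date = date,
        unique_sample_id = pw$unique_sample_id,
        method_name = method_name,
        polarity = pol,
        stringsAsFactors = FALSE
      )
    }
  }
  seq_df <- do.call(rbind, rows)
  seq_df$filename <- sprintf("%s_%s_%s_%s",
                             format(date, "%Y%m%d"),
                             seq_df$unique_sample_id,
                             method_name, seq_df$polarity)
  seq_df$injection_index <- seq_len(nrow(seq_df))
  rownames(seq_df) <- NULL
  if (!is.null(path)) utils::write.csv(seq_df, path, row.names = FALSE)
  seq_df
}

#' Collapse a compound table to one row per well
#'
#' @param metadata data.frame with `library_code`, `plate`, `well` (and
#'   optionally `unique_sample_id`).
#' @return the first row of each well, in order of appearance.
#' @export
unique_wells <- function(metadata) {
  if (!"unique_sample_id" %in% names(metadata)) {
    metadata <- assign_sample_ids(metadata)
  }
  metadata[!duplicated(metadata$unique_sample_id), , drop = FALSE]
}
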