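SPEC_TYPES <- c("SINGLE_BEST_SCAN", "SAME_ENERGY", "ALL_ENERGIES",
                "ALL_MSN_TO_PSEUDO_MS2")

#' Construct a spectral library entry
#'
#' An exportable annotated spectrum: the compound metadata it is attributed
#' to, the adduct, the precursor m/z, the merge level that produced it
#' (`spec_type`), quality scores and provenance back to the source scans.
#'
#' @param name compound name.
#' @param precursor_mz precursor m/z (Th).
#' @param mz,intensity peak vectors (sorted ascending by m/z; non-empty).
#' @param ms_level MS level of the spectrum (>= 2; a pseudo-MS2 composite is
#'   recorded as level 2).
#' @param spec_type one of `"SINGLE_BEST_SCAN"`, `"SAME_ENERGY"`,
#'   `"ALL_ENERGIES"`, `"ALL_MSN_TO_PSEUDO_MS2"`.
#' @param collision_energies numeric vector of the collision energies that
#'   contributed; `SAME_ENERGY` entries must list exactly one distinct
#'   energy.
#' @param adduct_name adduct label, e.g. `"[M+H]+"`.
#' @param polarity `"positive"` or `"negative"`.
#' @param formula,smiles,inchi,inchikey compound descriptors (optional).
#' @param precursor_purity_pct precursor isolation purity in percent, or
#'   `NA` when not scored.
#' @param chimeric_flag `TRUE` when the purity score marks the isolation as
#'   chimeric.
#' @param source_file,scan_numbers provenance of the member scans.
#' @return object of class `library_entry`.
#' @export
library_entry <- function(name, precursor_mz, mz, intensity,
                          ms_level = 2L, spec_type = "SINGLE_BEST_SCAN",
                          collision_energies = numeric(0),
                          adduct_name = NA_character_,
                          polarity = "positive",
                          formula = NA_character_, smiles = NA_character_,
                          inchi = NA_character_, inchikey = NA_character_,
                          precursor_purity_pct = NA_real_,
                          chimeric_flag = FALSE,
                          source_file = NA_character_,
                          scan_numbers = integer(0)) {
  spec_type <- match.arg(spec_type, SPEC_TYPES)
  polarity <- match.arg(polarity, c("positive", "negative"))
  stopifnot(length(mz) == length(intensity), precursor_mz > 0, ms_level >= 2)
  if (!length(mz)) stop("library entry must have a non-empty peak list")
  if (any(intensity < 0)) stop("negative peak intensity")
  ord <- order(mz)
  mz <- as.numeric(mz[ord]); intensity <- as.numeric(intensity[ord])
  collision_energies <- sort(unique(as.numeric(collision_energies)))
  if (spec_type == "SAME_ENERGY" && length(collision_energies) != 1L) {
    stop("SAME_ENERGY entries must list exactly one distinct collision energy")
  }
  if (!is.na(precursor_purity_pct) &&
      (precursor_purity_pct < 0 || precursor_purity_pct > 100)) {
    stop("precursor_purity_pct must lie in [0, 100]")
  }
  structure(list(
    name = as.character(name), adduct_name = as.character(adduct_name),
    precursor_mz = as.numeric(precursor_mz), ms_level = as.integer(ms_level),
    spec_type = spec_type,
    collision_energies = collision_energies,
    polarity = polarity,
    formula = as.character(formula), smiles = as.character(smiles),
    inchi = as.character(inchi), inchikey = as.character(inchikey),
    precursor_purity_pct = as.numeric(precursor_purity_pct),
    chimeric_flag = isTRUE(chimeric_flag),
    source_file = as.character(source_file),
    scan_numbers = as.integer(scan_numbers),
    mz = mz, intensity = intensity
  ), class = "library_entry")
}

#' @export
print.library_entry <- function(x, ...) {
  cat(sprintf("<library_entry %s %s m/z %.4f MS%d %s  %d peaks>\n",
              x$name, x$adduct_name, x$precursor_mz, x$ms_level,
              x$spec_type, length(x$mz)))
  invisible(x)
}

# full-precision float text so write -> read round-trips doubles exactly
fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    formatC(v, digits = 17, format = "g", width = -1)
  }, character(1L))
}

#' Write a spectral library
#'
#' Serializes library entries to one of the open library formats: GNPS-style
#' MGF, NIST-style MSP, or the package's JSON schema (a one-to-one mirror of
#' the entry fields). All metadata and peak values are written at full float
#' precision so a write/read cycle is the identity.
#'
#' @param entries list of [library_entry()] objects.
#' @param path output file.
#' @param format `"auto"` (by extension), `"mgf"`, `"msp"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_library <- function(entries, path, format = c("auto", "mgf", "msp", "json")) {
  format <- resolve_library_format(path, match.arg(format))
  stopifnot(is.list(entries))
  lapply(entries, function(e) {
    if (!inherits(e, "library_entry")) stop("entries must be library_entry objects")
  })
  switch(format,
         mgf = write_library_mgf(entries, path),
         msp = write_library_msp(entries, path),
         json = write_library_json(entries, path))
  invisible(path)
}

resolve_library_format <- function(path, format) {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("mgf", "msp", "json")) return(ext)
  stop("cannot infer library format from extension: ", path)
}

entry_kv <- function(e) {
  kv <- c(
    NAME = e$name,
    ADDUCT = e$adduct_name,
    FORMULA = e$formula,
    SMILES = e$smiles,
    INCHI = e$inchi,
    INCHIKEY = e$inchikey,
    MSLEVEL = as.character(e$ms_level),
    SPECTYPE = e$spec_type,
    COLLISION_ENERGY = paste(fmt_num(e$collision_energies), collapse = ","),
    IONMODE = e$polarity,
    PRECURSOR_PURITY = fmt_num(e$precursor_purity_pct),
    CHIMERIC = if (e$chimeric_flag) "true" else "false",
    SOURCE_FILE = e$source_file,
    SCAN_NUMBERS = paste(e$scan_numbers, collapse = ",")
  )
  kv[!is.na(kv) & kv != "NA"]
}

write_library_mgf <- function(entries, path) {
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  for (e in entries) {
    kv <- entry_kv(e)
    writeLines("BEGIN IONS", con)
    writeLines(sprintf("PEPMASS=%s", fmt_num(e$precursor_mz)), con)
    writeLines(sprintf("CHARGE=1%s", if (e$polarity == "positive") "+" else "-"), con)
    writeLines(sprintf("%s=%s", names(kv), unname(kv)), con)
    writeLines(sprintf("%s %s", fmt_num(e$mz), fmt_num(e$intensity)), con)
    writeLines(c("END IONS", ""), con)
  }
}

write_library_msp <- function(entries, path) {
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  for (e in entries) {
    kv <- entry_kv(e)
    kv <- kv[names(kv) != "NAME"]
    writeLines(sprintf("Name: %s", e$name), con)
    writeLines(sprintf("PrecursorMZ: %s", fmt_num(e$precursor_mz)), con)
    # NIST-style capitalized keys
    nice <- c(ADDUCT = "Precursor_type", FORMULA = "Formula",
              SMILES = "SMILES", INCHI = "InChI", INCHIKEY = "InChIKey",
              MSLEVEL = "MS_level", SPECTYPE = "Spec_type",
              COLLISION_ENERGY = "Collision_energy", IONMODE = "Ion_mode",
              PRECURSOR_PURITY = "Precursor_purity", CHIMERIC = "Chimeric",
              SOURCE_FILE = "Source_file", SCAN_NUMBERS = "Scan_numbers")
    writeLines(sprintf("%s: %s", nice[names(kv)], unname(kv)), con)
    writeLines(sprintf("Num Peaks: %d", length(e$mz)), con)
    writeLines(sprintf("%s %s", fmt_num(e$mz), fmt_num(e$intensity)), con)
    writeLines("", con)
  }
}

write_library_json <- function(entries, path) {
  recs <- lapply(entries, function(e) {
    r <- unclass(e)
    r$collision_energies <- I(r$collision_energies)
    r$scan_numbers <- I(r$scan_numbers)
    r$mz <- I(r$mz)
    r$intensity <- I(r$intensity)
    r
  })
  jsonlite::write_json(list(format = "msn-library", version = 1L,
                            entries = recs),
                       path, auto_unbox = TRUE, digits = I(17), na = "null")
}

#' Read a spectral library
#'
#' Inverse of [write_library()] for self-produced files; tolerant of
#' common foreign key variants in MGF and MSP input (lower-case keys,
#' `PRECURSORMZ`, `TITLE`, `Precursor_type`, ...). Records without peaks
#' are skipped and counted in the `n_skipped` attribute.
#'
#' @param path library file.
#' @param format `"auto"` (by extension), `"mgf"`, `"msp"` or `"json"`.
#' @return list of [library_entry()] objects, attribute `n_skipped`.
#' @export
read_library <- function(path, format = c("auto", "mgf", "msp", "json")) {
  format <- resolve_library_format(path, match.arg(format))
  if (!file.exists(path)) stop("library file not found: ", path)
  switch(format,
         mgf = read_library_mgf(path),
         msp = read_library_msp(path),
         json = read_library_json(path))
}

# alias table for foreign metadata keys (upper-cased before lookup)
MGF_KEY_ALIASES <- c(
  PEPMASS = "precursor_mz", PRECURSORMZ = "precursor_mz",
  PRECURSOR_MZ = "precursor_mz",
  NAME = "name", TITLE = "name", COMPOUND_NAME = "name",
  ADDUCT = "adduct_name", PRECURSOR_TYPE = "adduct_name",
  PRECURSORTYPE = "adduct_name",
  FORMULA = "formula", MOLECULAR_FORMULA = "formula",
  SMILES = "smiles", INCHI = "inchi",
  INCHIKEY = "inchikey", INCHIAUX = "inchikey",
  MSLEVEL = "ms_level", MS_LEVEL = "ms_level",
  SPECTYPE = "spec_type", SPEC_TYPE = "spec_type",
  COLLISION_ENERGY = "collision_energies", COLLISIONENERGY = "collision_energies",
  IONMODE = "polarity", ION_MODE = "polarity", POLARITY = "polarity",
  PRECURSOR_PURITY = "precursor_purity_pct", PURITY = "precursor_purity_pct",
  CHIMERIC = "chimeric_flag",
  SOURCE_FILE = "source_file", SCAN_NUMBERS = "scan_numbers",
  CHARGE = "charge"
)

entry_from_fields <- function(fields, mz, intensity, where) {
  if (!length(mz)) return(NULL)
  pol <- fields$polarity
  if (is.null(pol) && !is.null(fields$charge)) {
    pol <- if (grepl("-", fields$charge)) "negative" else "positive"
  }
  if (is.null(pol)) pol <- "positive"
  pol <- if (grepl("^n|^-", tolower(pol))) "negative" else "positive"
  pmz <- suppressWarnings(as.numeric(fields$precursor_mz))
  if (!length(pmz) || is.na(pmz)) {
    stop("library record without precursor m/z at ", where)
  }
  ces <- fields$collision_energies
  ces <- if (is.null(ces)) numeric(0) else
    suppressWarnings(as.numeric(strsplit(ces, ",")[[1L]]))
  sns <- fields$scan_numbers
  sns <- if (is.null(sns)) integer(0) else
    suppressWarnings(as.integer(strsplit(sns, ",")[[1L]]))
  spec_type <- fields$spec_type
  if (is.null(spec_type) || !spec_type %in% SPEC_TYPES) {
    spec_type <- "SINGLE_BEST_SCAN"
  }
  get_chr <- function(k) if (is.null(fields[[k]])) NA_character_ else fields[[k]]
  lvl <- suppressWarnings(as.integer(get_chr("ms_level")))
  purity <- suppressWarnings(as.numeric(get_chr("precursor_purity_pct")))
  library_entry(
    name = get_chr("name"), precursor_mz = pmz, mz = mz, intensity = intensity,
    ms_level = if (is.na(lvl)) 2L else lvl,
    spec_type = spec_type, collision_energies = ces[!is.na(ces)],
    adduct_name = get_chr("adduct_name"), polarity = pol,
    formula = get_chr("formula"), smiles = get_chr("smiles"),
    inchi = get_chr("inchi"), inchikey = get_chr("inchikey"),
    precursor_purity_pct = purity,
    chimeric_flag = isTRUE(tolower(get_chr("chimeric_flag")) %in%
                             c("true", "1", "yes")),
    source_file = get_chr("source_file"), scan_numbers = sns[!is.na(sns)]
  )
}

read_library_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  entries <- list()
  skipped <- 0L
  i <- 1L; n <- length(lines); rec <- 0L
  while (i <= n) {
    if (trimws(lines[i]) != "BEGIN IONS") { i <- i + 1L; next }
    rec <- rec + 1L
    fields <- list(); mz <- numeric(0); int <- numeric(0)
    i <- i + 1L
    closed <- FALSE
    while (i <= n) {
      ln <- trimws(lines[i])
      i <- i + 1L
      if (ln == "END IONS") { closed <- TRUE; break }
      if (!nzchar(ln)) next
      if (grepl("=", ln, fixed = TRUE)) {
        key <- toupper(sub("=.*$", "", ln))
        val <- sub("^[^=]*=", "", ln)
        std <- MGF_KEY_ALIASES[key]
        if (!is.na(std)) fields[[unname(std)]] <- trimws(val)
      } else {
        parts <- strsplit(ln, "[ \t]+")[[1L]]
        v <- suppressWarnings(as.numeric(parts[1:2]))
        if (any(is.na(v))) stop("malformed peak line in MGF record ", rec,
                                ": '", ln, "'")
        mz <- c(mz, v[1L]); int <- c(int, v[2L])
      }
    }
    if (!closed) stop("truncated MGF file: record ", rec,
                      " has no END IONS (", basename(path), ")")
    e <- entry_from_fields(fields, mz, int, paste0("MGF record ", rec))
    if (is.null(e)) skipped <- skipped + 1L else entries[[length(entries) + 1L]] <- e
  }
  finish_library_read(entries, skipped, path)
}

MSP_KEY_ALIASES <- c(
  NAME = "name", PRECURSORMZ = "precursor_mz", PRECURSOR_MZ = "precursor_mz",
  PRECURSOR_TYPE = "adduct_name", PRECURSORTYPE = "adduct_name",
  ADDUCT = "adduct_name", FORMULA = "formula",
  SMILES = "smiles", INCHI = "inchi", INCHIKEY = "inchikey",
  MS_LEVEL = "ms_level", MSLEVEL = "ms_level", SPECTRUM_TYPE = "ms_level_word",
  SPEC_TYPE = "spec_type", SPECTYPE = "spec_type",
  COLLISION_ENERGY = "collision_energies", ION_MODE = "polarity",
  IONMODE = "polarity", PRECURSOR_PURITY = "precursor_purity_pct",
  CHIMERIC = "chimeric_flag", SOURCE_FILE = "source_file",
  SCAN_NUMBERS = "scan_numbers", CHARGE = "charge"
)

read_library_msp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  entries <- list()
  skipped <- 0L
  i <- 1L; n <- length(lines); rec <- 0L
  while (i <= n) {
    if (!grepl("^name:", lines[i], ignore.case = TRUE)) { i <- i + 1L; next }
    rec <- rec + 1L
    fields <- list(name = trimws(sub("^[Nn][Aa][Mm][Ee]:", "", lines[i])))
    i <- i + 1L
    npeaks <- NA_integer_
    while (i <= n && grepl(":", lines[i], fixed = TRUE) &&
           !grepl("^name:", lines[i], ignore.case = TRUE)) {
      key <- toupper(gsub("[ -]", "_", sub(":.*$", "", lines[i])))
      val <- trimws(sub("^[^:]*:", "", lines[i]))
      i <- i + 1L
      if (key == "NUM_PEAKS") { npeaks <- as.integer(val); break }
      std <- MSP_KEY_ALIASES[key]
      if (!is.na(std)) fields[[unname(std)]] <- val
    }
    if (!is.null(fields$ms_level_word)) {
      lvl <- suppressWarnings(as.integer(sub("^MS", "", toupper(fields$ms_level_word))))
      if (!is.na(lvl)) fields$ms_level <- as.character(lvl)
      fields$ms_level_word <- NULL
    }
    if (is.na(npeaks)) {
      stop("truncated MSP file: record ", rec, " ('", fields$name,
           "') has no Num Peaks line (", basename(path), ")")
    }
    mz <- numeric(0); int <- numeric(0)
    while (i <= n && length(mz) < npeaks) {
      ln <- trimws(lines[i])
      i <- i + 1L
      if (!nzchar(ln)) next
      # NIST dialect allows several ";"-separated peaks per line
      for (chunk in trimws(strsplit(ln, ";", fixed = TRUE)[[1L]])) {
        if (!nzchar(chunk)) next
        parts <- strsplit(chunk, "[ \t]+")[[1L]]
        v <- suppressWarnings(as.numeric(parts[1:2]))
        if (any(is.na(v))) stop("malformed peak line in MSP record ", rec,
                                ": '", ln, "'")
        mz <- c(mz, v[1L]); int <- c(int, v[2L])
      }
    }
    if (length(mz) < npeaks) {
      stop("truncated MSP file: record ", rec, " promises ", npeaks,
           " peaks, found ", length(mz), " (", basename(path), ")")
    }
    e <- entry_from_fields(fields, mz, int, paste0("MSP record ", rec))
    if (is.null(e)) skipped <- skipped + 1L else entries[[length(entries) + 1L]] <- e
  }
  finish_library_read(entries, skipped, path)
}

read_library_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  recs <- if (!is.null(doc$entries)) doc$entries else doc
  entries <- list()
  skipped <- 0L
  json_chr <- function(x) if (is.null(x)) NA_character_ else as.character(x)
  json_num <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  for (k in seq_along(recs)) {
    r <- recs[[k]]
    mz <- as.numeric(unlist(r$mz))
    int <- as.numeric(unlist(r$intensity))
    if (!length(mz)) { skipped <- skipped + 1L; next }
    entries[[length(entries) + 1L]] <- library_entry(
      name = json_chr(r$name), precursor_mz = as.numeric(r$precursor_mz),
      mz = mz, intensity = int,
      ms_level = if (is.null(r$ms_level)) 2L else as.integer(r$ms_level),
      spec_type = if (is.null(r$spec_type)) "SINGLE_BEST_SCAN" else r$spec_type,
      collision_energies = as.numeric(unlist(r$collision_energies)),
      adduct_name = json_chr(r$adduct_name),
      polarity = if (is.null(r$polarity)) "positive" else r$polarity,
      formula = json_chr(r$formula), smiles = json_chr(r$smiles),
      inchi = json_chr(r$inchi), inchikey = json_chr(r$inchikey),
      precursor_purity_pct = json_num(r$precursor_purity_pct),
      chimeric_flag = isTRUE(r$chimeric_flag),
      source_file = json_chr(r$source_file),
      scan_numbers = as.integer(unlist(r$scan_numbers))
    )
  }
  finish_library_read(entries, skipped, path)
}

finish_library_read <- function(entries, skipped, path) {
  if (skipped > 0L) {
    warning(skipped, " record(s) without peaks skipped in ", basename(path))
  }
  attr(entries, "n_skipped") <- skipped
  entries
}
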