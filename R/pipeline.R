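#' Build a spectral library from scan files and curated metadata
#'
#' The end-to-end automated library-generation pipeline. Per scan file:
#' read scans, denoise (noise factor at all MS levels) and remove known
#' background ions, assemble MSn trees, annotate tree roots against the
#' compounds known to be in the sample (matched from the file name's unique
#' sample identifier), score precursor isolation purity from the flanking
#' MS1 scans, derive best/merged spectra at every level (SINGLE_BEST_SCAN,
#' SAME_ENERGY, ALL_ENERGIES and the tree-collapsing
#' ALL_MSN_TO_PSEUDO_MS2), drop spectra with fewer than `min_signals`
#' peaks, and export per polarity in the requested formats.
#'
#' @param metadata curated compound table ([curate_compounds()] output or
#'   equivalent, with `unique_sample_id`, `monoisotopic_mass`, `inchikey`).
#' @param scan_files character vector of scan file paths.
#' @param out_dir output directory for library files and the run report.
#' @param formats library formats to write (subset of mgf/msp/json).
#' @param adducts adduct table ([default_adducts()]).
#' @param noise_factor noise filter factor (all MS levels).
#' @param background_windows exclusion windows
#'   ([default_background_windows()]).
#' @param tree_mz_tol precursor-chain matching tolerance (Th).
#' @param bin_mz_tol spectral merging tolerance (Th).
#' @param tol_ppm,tol_abs annotation tolerance (combined as max).
#' @param min_signals minimum peaks for library export.
#' @param chimeric_threshold purity percentage below which entries are
#'   flagged chimeric.
#' @param isolation_width fallback isolation width for purity scoring when
#'   a scan does not carry one.
#' @return (invisibly) list with `entries` (per polarity), `report`, and
#'   `files` (paths written). The report is also written as `report.json`.
#' @export
build_library <- function(metadata, scan_files, out_dir,
                          formats = c("mgf", "msp", "json"),
                          adducts = default_adducts(),
                          noise_factor = 2.5,
                          background_windows = default_background_windows(),
                          tree_mz_tol = 0.01,
                          bin_mz_tol = 0.005,
                          tol_ppm = 10, tol_abs = 0.005,
                          min_signals = 2L,
                          chimeric_threshold = 90,
                          isolation_width = 1.2) {
  stopifnot(is.data.frame(metadata), length(scan_files) >= 1,
            all(formats %in% c("mgf", "msp", "json")))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  entries <- list(positive = list(), negative = list())
  file_reports <- list()
  detected <- list(positive = character(0), negative = character(0))
  failures <- 0L

  for (path in scan_files) {
    rep1 <- tryCatch(
      process_one_file(path, metadata, adducts, noise_factor,
                       background_windows, tree_mz_tol, bin_mz_tol,
                       tol_ppm, tol_abs, min_signals, chimeric_threshold,
                       isolation_width),
      error = function(e) {
        warning("skipping ", basename(path), ": ", conditionMessage(e))
        NULL
      })
    if (is.null(rep1)) { failures <- failures + 1L; next }
    pol <- rep1$polarity
    entries[[pol]] <- c(entries[[pol]], rep1$entries)
    detected[[pol]] <- union(detected[[pol]], rep1$detected_inchikeys)
    file_reports[[length(file_reports) + 1L]] <- rep1$counts
  }
  if (failures == length(scan_files)) {
    stop("all ", failures, " scan files failed to process")
  }

  written <- character(0)
  for (pol in c("positive", "negative")) {
    if (!length(entries[[pol]])) next
    for (fmt in formats) {
      f <- file.path(out_dir, sprintf("library_%s.%s", pol, fmt))
      write_library(entries[[pol]], f, format = fmt)
      written <- c(written, f)
    }
  }

  pol_sets <- Filter(length, detected)
  polarity_overlap <- if (length(pol_sets)) {
    ov <- overlap_sets(pol_sets)
    ov[c("pattern_counts", "per_source_unique", "union_size")]
  } else NULL

  n_sourced <- length(unique(metadata$inchikey))
  n_detected <- length(unique(unlist(detected, use.names = FALSE)))
  report <- list(
    n_files = length(scan_files),
    n_files_failed = failures,
    files = do.call(rbind, file_reports),
    compounds_sourced = n_sourced,
    compounds_detected = n_detected,
    coverage_pct = coverage_pct(n_detected, n_sourced),
    detected_by_polarity = lapply(detected, length),
    polarity_overlap = polarity_overlap,
    n_entries = lapply(entries, length)
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       na = "null", force = TRUE)
  invisible(list(entries = entries, report = report, files = written))
}

process_one_file <- function(path, metadata, adducts, noise_factor,
                             background_windows, tree_mz_tol, bin_mz_tol,
                             tol_ppm, tol_abs, min_signals,
                             chimeric_threshold, isolation_width) {
  scans <- read_scans(path)
  if (!length(scans)) stop("no scans in file")
  source_file <- attr(scans, "source_file")
  polarity <- scans[[1L]]$polarity

  filtered <- lapply(scans, function(s) {
    remove_background(noise_filter(s, noise_factor), background_windows)
  })

  candidates <- compounds_for_file(source_file, metadata)

  msn <- Filter(function(s) s$ms_level >= 2L, filtered)
  forest <- build_trees(msn, mz_tol = tree_mz_tol)
  annotations <- annotate_forest(forest, candidates, adducts,
                                 polarity = polarity,
                                 tol_ppm = tol_ppm, tol_abs = tol_abs)

  # purity of each annotated root from the MS1 scans flanking its MS2
  # member scans (filtered peaks, scale-invariant score)
  ms1_idx <- which(vapply(filtered, function(s) s$ms_level == 1L, logical(1L)))
  ms1_numbers <- vapply(filtered[ms1_idx], `[[`, integer(1L), "scan_number")
  root_purity <- function(root) {
    vals <- vapply(root$scans, function(sc) {
      before_i <- ms1_idx[ms1_numbers < sc$scan_number]
      if (!length(before_i)) return(NA_real_)
      after_i <- ms1_idx[ms1_numbers > sc$scan_number]
      width <- sc$precursor_chain$isolation_width[1L]
      if (is.na(width) || width <= 0) width <- isolation_width
      pr <- precursor_purity(
        before = filtered[[before_i[length(before_i)]]],
        after = if (length(after_i)) filtered[[after_i[1L]]] else NULL,
        precursor_mz = sc$precursor_chain$precursor_mz[1L],
        isolation_width = width,
        chimeric_threshold = chimeric_threshold)
      pr$purity_pct
    }, numeric(1L))
    vals <- vals[!is.na(vals)]
    if (!length(vals)) NA_real_ else mean(vals)
  }

  out_entries <- list()
  detected <- character(0)
  if (nrow(annotations)) {
    for (ri in unique(annotations$root)) {
      root <- forest[[ri]]
      ann_rows <- annotations[annotations$root == ri, , drop = FALSE]
      purity <- root_purity(root)
      chim <- !is.na(purity) && purity < chimeric_threshold
      specs <- tree_spectra(root, bin_mz_tol)
      for (k in seq_len(nrow(ann_rows))) {
        a <- ann_rows[k, ]
        detected <- union(detected, a$inchikey)
        for (sp in specs) {
          if (!min_signal_filter(sp$spectrum$mz, min_signals)) next
          out_entries[[length(out_entries) + 1L]] <- library_entry(
            name = if (!is.null(a$name)) a$name else a$inchikey,
            adduct_name = a$adduct_name,
            precursor_mz = sp$precursor_mz,
            mz = sp$spectrum$mz, intensity = sp$spectrum$intensity,
            ms_level = sp$ms_level, spec_type = sp$spec_type,
            collision_energies = sp$energies,
            polarity = polarity,
            formula = one_of(a, "formula"), smiles = one_of(a, "cleaned_smiles"),
            inchi = one_of(a, "inchi"), inchikey = a$inchikey,
            precursor_purity_pct = purity, chimeric_flag = chim,
            source_file = source_file, scan_numbers = sp$scan_numbers)
        }
      }
    }
  }

  counts <- data.frame(
    file = source_file, polarity = polarity,
    n_scans = length(scans),
    n_msn_scans = length(msn),
    n_trees = sum(vapply(forest, function(r) !r$orphan, logical(1L))),
    n_orphans = sum(vapply(forest, `[[`, logical(1L), "orphan")),
    n_candidates = nrow(candidates),
    n_annotated_roots = length(unique(annotations$root)),
    n_entries = length(out_entries),
    stringsAsFactors = FALSE)

  list(polarity = polarity, entries = out_entries,
       detected_inchikeys = detected, counts = counts)
}

one_of <- function(row, col) {
  if (col %in% names(row)) as.character(row[[col]]) else NA_character_
}

# all exportable spectra of one tree: per node the best scan per energy,
# the same-energy consensus where repeat triggers exist, the all-energies
# merge; plus the root's pseudo-MS2
tree_spectra <- function(root, bin_mz_tol) {
  specs <- list()
  push <- function(spec_type, node_mz, ms_level, spectrum, energies,
                   scan_numbers) {
    if (!length(spectrum$mz)) return(invisible())
    specs[[length(specs) + 1L]] <<- list(
      spec_type = spec_type, precursor_mz = node_mz, ms_level = ms_level,
      spectrum = list(mz = spectrum$mz, intensity = spectrum$intensity),
      energies = energies, scan_numbers = scan_numbers)
  }
  for (node in tree_nodes(root)) {
    for (e in node_energies(node)) {
      best <- select_best_scan(node, e)
      if (!is.null(best)) {
        push("SINGLE_BEST_SCAN", node$precursor_mz, node$ms_level,
             as_spectrum(best), e, best$scan_number)
      }
      cons <- merge_same_energy(node, e, mz_tol = bin_mz_tol)
      if (!is.null(cons)) {
        push("SAME_ENERGY", node$precursor_mz, node$ms_level, cons, e,
             attr(cons, "scan_numbers"))
      }
    }
    all_e <- merge_all_energies(node, mz_tol = bin_mz_tol)
    if (!is.null(all_e)) {
      push("ALL_ENERGIES", node$precursor_mz, node$ms_level, all_e,
           attr(all_e, "energies"), attr(all_e, "scan_numbers"))
    }
  }
  if (root$ms_level == 2L) {
    ps <- build_pseudo_ms2(root, mz_tol = bin_mz_tol)
    push("ALL_MSN_TO_PSEUDO_MS2", root$precursor_mz, 2L, ps,
         attr(ps, "energies"), attr(ps, "scan_numbers"))
  }
  specs
}
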