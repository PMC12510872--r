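#' Construct a centroided MSn scan record
#'
#' The unit record of the pipeline: one centroided scan at any MS level,
#' carrying its full precursor chain (one row per isolation/fragmentation
#' stage from the MS2 selection down to this scan's own stage).
#'
#' The minimum raw peak intensity is stored as the scan's `noise_floor` at
#' construction time. Noise filtering thresholds against this stored floor,
#' so denoising is idempotent and commutes with background-window removal.
#'
#' @param scan_number acquisition scan number (>= 1).
#' @param ms_level MS level (>= 1).
#' @param polarity `"positive"` or `"negative"`.
#' @param retention_time retention time in minutes.
#' @param mz,intensity numeric peak vectors (re-sorted ascending by m/z).
#' @param precursor_chain data.frame with `precursor_mz`,
#'   `isolation_width`, `collision_energy`; must have `ms_level - 1` rows.
#' @param noise_floor optional fixed noise floor; defaults to
#'   `min(intensity)` (0 for an empty scan).
#' @return object of class `msn_scan`.
#' @export
msn_scan <- function(scan_number, ms_level, polarity, retention_time,
                     mz, intensity, precursor_chain = NULL,
                     noise_floor = NULL) {
  stopifnot(length(scan_number) == 1L, scan_number >= 1,
            length(ms_level) == 1L, ms_level >= 1,
            length(mz) == length(intensity))
  polarity <- match.arg(polarity, c("positive", "negative"))
  if (is.null(precursor_chain)) {
    precursor_chain <- empty_precursor_chain()
  }
  precursor_chain <- as.data.frame(precursor_chain)
  for (col in intersect(c("precursor_mz", "isolation_width",
                          "collision_energy"), names(precursor_chain))) {
    precursor_chain[[col]] <- as.numeric(precursor_chain[[col]])
  }
  if (nrow(precursor_chain) != ms_level - 1L) {
    stop("precursor_chain must have ms_level - 1 = ", ms_level - 1L,
         " rows, got ", nrow(precursor_chain))
  }
  if (nrow(precursor_chain) && any(precursor_chain$precursor_mz <= 0)) {
    stop("precursor m/z must be positive")
  }
  if (any(intensity < 0)) stop("negative peak intensity")
  ord <- order(mz)
  mz <- as.numeric(mz[ord]); intensity <- as.numeric(intensity[ord])
  if (anyDuplicated(mz)) {
    # strict ascending m/z: collapse exact duplicates by summed intensity
    intensity <- as.numeric(tapply(intensity, factor(mz, levels = unique(mz)), sum))
    mz <- unique(mz)
  }
  if (is.null(noise_floor)) {
    noise_floor <- if (length(intensity)) min(intensity) else 0
  }
  structure(list(
    scan_number = as.integer(scan_number),
    ms_level = as.integer(ms_level),
    polarity = polarity,
    retention_time = as.numeric(retention_time),
    mz = mz,
    intensity = intensity,
    precursor_chain = precursor_chain[, c("precursor_mz", "isolation_width",
                                          "collision_energy"), drop = FALSE],
    tic = sum(intensity),
    noise_floor = as.numeric(noise_floor)
  ), class = "msn_scan")
}

empty_precursor_chain <- function() {
  data.frame(precursor_mz = numeric(0), isolation_width = numeric(0),
             collision_energy = numeric(0))
}

precursor_step <- function(precursor_mz, isolation_width, collision_energy) {
  stopifnot(precursor_mz > 0, isolation_width > 0, collision_energy >= 0)
  data.frame(precursor_mz = precursor_mz, isolation_width = isolation_width,
             collision_energy = collision_energy)
}

#' @export
print.msn_scan <- function(x, ...) {
  cat(sprintf("<msn_scan #%d MS%d %s  %d peaks  TIC %.3g  RT %.2f min>\n",
              x$scan_number, x$ms_level, x$polarity, length(x$mz), x$tic,
              x$retention_time))
  if (nrow(x$precursor_chain)) {
    chain <- paste(sprintf("%.4f@%geV", x$precursor_chain$precursor_mz,
                           x$precursor_chain$collision_energy),
                   collapse = " -> ")
    cat("  chain:", chain, "\n")
  }
  invisible(x)
}

# collision energy of a scan's own (deepest) fragmentation stage
scan_energy <- function(scan) {
  n <- nrow(scan$precursor_chain)
  if (!n) return(NA_real_)
  scan$precursor_chain$collision_energy[n]
}

scan_precursor_mz <- function(scan) {
  n <- nrow(scan$precursor_chain)
  if (!n) return(NA_real_)
  scan$precursor_chain$precursor_mz[n]
}

#' Read centroided MSn scans
#'
#' Reads a scan file into a list of [msn_scan()] records in acquisition
#' order. Two formats are supported: standard mzML (via mzR) and the
#' package's versioned JSON scan dialect ("scanjson") used for text-only
#' fixtures and simulator output.
#'
#' For mzML input the full precursor chain of an MSn scan is reconstructed
#' by walking up the most recent ancestor scan at each lower level when the
#' file stores only the immediate precursor. MSn scans lacking precursor
#' information are excluded and counted (attribute `n_excluded`, with a
#' warning). Files mixing polarities are rejected: polarities are acquired
#' in separate runs.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"mzml"` or `"scanjson"`.
#' @return list of `msn_scan` objects with attributes `source_file` and
#'   `n_excluded`.
#' @export
read_scans <- function(path, format = c("auto", "mzml", "scanjson")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "mzml") "mzml" else "scanjson"
  }
  if (!file.exists(path)) stop("scan file not found: ", path)
  scans <- switch(format,
                  mzml = read_scans_mzml(path),
                  scanjson = read_scans_scanjson(path))
  pols <- unique(vapply(scans, `[[`, character(1L), "polarity"))
  if (length(pols) > 1L) {
    stop("file mixes polarities (", paste(pols, collapse = ", "),
         "); polarities are acquired in separate runs: ", path)
  }
  if (!length(scans)) warning("no scans read from ", path)
  attr(scans, "source_file") <- basename(path)
  scans
}

read_scans_scanjson <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$format) || doc$format != "scanjson") {
    stop("not a scanjson file (missing format tag): ", path)
  }
  scans <- lapply(seq_along(doc$scans), function(i) {
    s <- doc$scans[[i]]
    tryCatch({
      chain <- if (length(s$precursors)) {
        do.call(rbind, lapply(s$precursors, function(p) {
          data.frame(precursor_mz = p$mz, isolation_width = p$width,
                     collision_energy = p$energy)
        }))
      } else NULL
      msn_scan(scan_number = s$scan_number, ms_level = s$ms_level,
               polarity = s$polarity, retention_time = s$retention_time,
               mz = unlist(s$mz), intensity = unlist(s$intensity),
               precursor_chain = chain,
               noise_floor = s$noise_floor)
    }, error = function(e) {
      stop("malformed scanjson record at scan index ", i, ": ",
           conditionMessage(e))
    })
  })
  scans
}

read_scans_mzml <- function(path) {
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh), add = TRUE)
  hd <- mzR::header(fh)
  n <- nrow(hd)
  scans <- vector("list", n)
  last_at_level <- list()  # level -> index into scans
  excluded <- 0L
  for (i in seq_len(n)) {
    lvl <- hd$msLevel[i]
    pol <- if (!is.na(hd$polarity[i]) && hd$polarity[i] == 0) "negative" else "positive"
    pk <- mzR::peaks(fh, i)
    chain <- NULL
    if (lvl > 1L) {
      pmz <- hd$precursorMZ[i]
      if (is.na(pmz) || pmz <= 0) {
        excluded <- excluded + 1L
        next
      }
      lo <- hd$isolationWindowLowerOffset[i]
      hi <- hd$isolationWindowUpperOffset[i]
      width <- if (is.na(lo) || is.na(hi)) 1.2 else lo + hi
      ce <- hd$collisionEnergy[i]
      step <- precursor_step(pmz, width, if (is.na(ce)) 0 else ce)
      parent_chain <- NULL
      if (lvl > 2L) {
        # prefer the scan named by precursorScanNum; else the most recent
        # scan one level up
        pscan <- hd$precursorScanNum[i]
        pidx <- if (!is.na(pscan) && pscan > 0) {
          w <- which(hd$acquisitionNum == pscan & seq_len(n) < i)
          if (length(w)) w[length(w)] else NA_integer_
        } else NA_integer_
        if (is.na(pidx)) pidx <- last_at_level[[as.character(lvl - 1L)]]
        if (is.null(pidx) || is.na(pidx) || is.null(scans[[pidx]])) {
          excluded <- excluded + 1L
          next
        }
        parent_chain <- scans[[pidx]]$precursor_chain
      }
      chain <- rbind(parent_chain, step)
    }
    scans[[i]] <- msn_scan(
      scan_number = hd$acquisitionNum[i], ms_level = lvl, polarity = pol,
      retention_time = hd$retentionTime[i] / 60,
      mz = pk[, 1L], intensity = pk[, 2L], precursor_chain = chain)
    last_at_level[[as.character(lvl)]] <- i
  }
  scans <- scans[!vapply(scans, is.null, logical(1L))]
  if (excluded > 0L) {
    warning(excluded, " MSn scan(s) lacking usable precursor information ",
            "were excluded from ", basename(path))
    attr(scans, "n_excluded") <- excluded
  } else {
    attr(scans, "n_excluded") <- 0L
  }
  scans
}

#' Write MSn scans
#'
#' Writes a list of [msn_scan()] records as scanjson (full float precision)
#' or mzML (via mzR).
#'
#' @param scans list of `msn_scan` objects.
#' @param path output path.
#' @param format `"scanjson"` or `"mzml"`.
#' @return `path`, invisibly.
#' @export
write_scans <- function(scans, path, format = c("scanjson", "mzml")) {
  format <- match.arg(format)
  switch(format,
         scanjson = write_scans_scanjson(scans, path),
         mzml = write_scans_mzml(scans, path))
  invisible(path)
}

write_scans_scanjson <- function(scans, path) {
  doc <- list(
    format = "scanjson",
    version = 1L,
    filename = basename(path),
    scans = lapply(scans, function(s) {
      rec <- list(scan_number = s$scan_number, ms_level = s$ms_level,
                  polarity = s$polarity, retention_time = s$retention_time,
                  noise_floor = s$noise_floor,
                  mz = s$mz, intensity = s$intensity)
      if (nrow(s$precursor_chain)) {
        rec$precursors <- lapply(seq_len(nrow(s$precursor_chain)), function(k) {
          list(mz = s$precursor_chain$precursor_mz[k],
               width = s$precursor_chain$isolation_width[k],
               energy = s$precursor_chain$collision_energy[k])
        })
      }
      rec
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17), pretty = FALSE)
}

write_scans_mzml <- function(scans, path) {
  n <- length(scans)
  stopifnot(n > 0)
  # precursorScanNum: the most recent earlier scan one level up whose own
  # chain is this scan's chain prefix (so sibling scans at other collision
  # energies are not mistaken for the parent); fall back to the most recent
  # scan at that level
  prec_scan <- integer(n)
  last_at_level <- list()
  chain_prefix_matches <- function(parent, child) {
    pc <- parent$precursor_chain
    cc <- child$precursor_chain
    if (nrow(pc) != nrow(cc) - 1L) return(FALSE)
    if (!nrow(pc)) return(TRUE)
    head_cc <- cc[seq_len(nrow(pc)), , drop = FALSE]
    all(abs(pc$precursor_mz - head_cc$precursor_mz) < 1e-9) &&
      all(abs(pc$collision_energy - head_cc$collision_energy) < 1e-9)
  }
  for (i in seq_len(n)) {
    lvl <- scans[[i]]$ms_level
    if (lvl > 1L) {
      p <- NA_integer_
      for (j in rev(seq_len(i - 1L))) {
        if (scans[[j]]$ms_level == lvl - 1L &&
            chain_prefix_matches(scans[[j]], scans[[i]])) { p <- j; break }
      }
      if (is.na(p)) p <- last_at_level[[as.character(lvl - 1L)]]
      prec_scan[i] <- if (is.null(p) || is.na(p)) 0L else scans[[p]]$scan_number
    }
    last_at_level[[as.character(lvl)]] <- i
  }
  num <- function(f) vapply(scans, function(s) as.numeric(f(s)), numeric(1L))
  int <- function(f) vapply(scans, function(s) as.integer(f(s)), integer(1L))
  safe_max <- function(x) if (length(x)) max(x) else 0
  last_step <- function(s, col, default = NA_real_) {
    k <- nrow(s$precursor_chain)
    if (k) s$precursor_chain[[col]][k] else default
  }
  hd <- data.frame(
    seqNum = seq_len(n),
    acquisitionNum = int(function(s) s$scan_number),
    msLevel = int(function(s) s$ms_level),
    polarity = int(function(s) if (s$polarity == "positive") 1L else 0L),
    peaksCount = int(function(s) length(s$mz)),
    totIonCurrent = num(function(s) s$tic),
    retentionTime = num(function(s) s$retention_time * 60),
    basePeakMZ = num(function(s) if (length(s$mz)) s$mz[which.max(s$intensity)] else 0),
    basePeakIntensity = num(function(s) safe_max(s$intensity)),
    collisionEnergy = num(function(s) {
      e <- last_step(s, "collision_energy"); if (is.na(e)) 0 else e
    }),
    ionisationEnergy = 0,
    lowMZ = num(function(s) if (length(s$mz)) min(s$mz) else 0),
    highMZ = num(function(s) safe_max(s$mz)),
    precursorScanNum = prec_scan,
    precursorMZ = num(function(s) {
      p <- last_step(s, "precursor_mz"); if (is.na(p)) 0 else p
    }),
    precursorCharge = int(function(s) if (s$ms_level > 1L) 1L else 0L),
    precursorIntensity = 0,
    mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0,
    filterString = vapply(scans, function(s)
      sprintf("ms%d %s", s$ms_level, s$polarity), character(1L)),
    spectrumId = sprintf("scan=%d", int(function(s) s$scan_number)),
    centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = num(function(s) last_step(s, "precursor_mz")),
    isolationWindowLowerOffset = num(function(s) last_step(s, "isolation_width") / 2),
    isolationWindowUpperOffset = num(function(s) last_step(s, "isolation_width") / 2),
    scanWindowLowerLimit = NA_real_,
    scanWindowUpperLimit = NA_real_,
    stringsAsFactors = FALSE
  )
  pk <- lapply(scans, function(s) cbind(mz = s$mz, intensity = s$intensity))
  mzR::writeMSData(pk, path, header = hd)
  invisible(path)
}
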