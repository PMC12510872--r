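#' Simulation configuration for pooled-well flow-injection MSn runs
#'
#' Defaults emulate the acquisition schema of the high-throughput MSn
#' method: top-3 data-dependent MS2 selection with three collision
#' energies (20 eV, 60 eV and an "assisted" energy picked per precursor
#' from 15-75 eV in 15 eV steps), top-5 MS3 at 20/40/60 eV from the
#' assisted MS2 scan, top-2 MS4 from the 40 eV MS3 scan, top-2 MS5 (40/60
#' eV, fragments above m/z 150) from the 40 eV MS4 scan, minimum-intensity
#' gates of 6e5/2e5 (MS2, positive/negative) and 2e4/1e4 (deeper levels),
#' each precursor re-selected up to three times before dynamic exclusion,
#' plus isotope envelopes, background ions, a noise floor and chimeric
#' co-isolation.
#'
#' @param seed integer seed for the run.
#' @param compounds_per_well pooled compounds per well (default 10).
#' @param adduct_probabilities named ionization probabilities per adduct.
#' @param fragments_per_level integer range of fragments drawn per node.
#' @param noise_peaks_per_scan integer range of noise peaks per scan.
#' @param noise_intensity_meanlog,noise_intensity_sdlog lognormal noise
#'   intensity parameters.
#' @param ion_intensity_meanlog,ion_intensity_sdlog lognormal compound-ion
#'   intensity parameters.
#' @param background_ions background ion table (`center_mz`, `intensity`).
#' @param chimera_rate probability that a compound ion is co-isolated with
#'   a contaminant of comparable intensity.
#' @param topn_ms2,topn_ms3,topn_ms4,topn_ms5 data-dependent selection
#'   breadth per level.
#' @param energies_ms2,energies_msn,energies_ms5 collision energy sets
#'   (eV); the MS2 set's `NA` slot is replaced by the per-precursor
#'   assisted energy.
#' @param assisted_energies candidate assisted collision energies.
#' @param min_intensity_ms2,min_intensity_msn selection gates per polarity.
#' @param repeat_triggers times a precursor is selected before exclusion.
#' @param max_ms_level deepest MS level acquired.
#' @param ms1_mz_range,msn_min_mz,ms5_min_mz m/z bounds of the schema.
#' @param isolation_width_ms2 MS2 isolation window width (Th).
#' @param mz_jitter_ppm 1-sigma mass error applied to observed m/z.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       compounds_per_well = 10L,
                       adduct_probabilities = c("[M+H]+" = 0.95,
                                                "[M+Na]+" = 0.35,
                                                "[M-H]-" = 0.9,
                                                "[M+HCOO]-" = 0.25),
                       fragments_per_level = c(3L, 8L),
                       noise_peaks_per_scan = c(5L, 15L),
                       noise_intensity_meanlog = log(4e3),
                       noise_intensity_sdlog = 0.6,
                       ion_intensity_meanlog = log(6e6),
                       ion_intensity_sdlog = 1.0,
                       background_ions = data.frame(
                         center_mz = c(149.72, 173.52),
                         intensity = c(3e4, 2e4)),
                       chimera_rate = 0.05,
                       topn_ms2 = 3L, topn_ms3 = 5L,
                       topn_ms4 = 2L, topn_ms5 = 2L,
                       energies_ms2 = c(20, 60, NA),
                       energies_msn = c(20, 40, 60),
                       energies_ms5 = c(40, 60),
                       assisted_energies = c(15, 30, 45, 60, 75),
                       min_intensity_ms2 = c(positive = 6e5, negative = 2e5),
                       min_intensity_msn = c(positive = 2e4, negative = 1e4),
                       repeat_triggers = 3L,
                       max_ms_level = 5L,
                       ms1_mz_range = c(115, 2000),
                       msn_min_mz = 90,
                       ms5_min_mz = 150,
                       isolation_width_ms2 = 1.2,
                       mz_jitter_ppm = 1) {
  stopifnot(all(adduct_probabilities >= 0 & adduct_probabilities <= 1),
            chimera_rate >= 0, chimera_rate <= 1,
            topn_ms2 > 0, topn_ms3 > 0, topn_ms4 > 0, topn_ms5 > 0,
            max_ms_level >= 2L)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

jitter_mz <- function(mz, ppm) mz * (1 + stats::rnorm(length(mz), 0, ppm * 1e-6))

# deterministic fragment skeleton for one precursor: random losses, always
# below the precursor and above min_mz (chemically naive on purpose: enough
# to exercise tree building, merging and matching)
draw_fragments <- function(precursor_mz, cfg, min_mz = 50) {
  lo <- max(min_mz, 0.15 * precursor_mz)
  hi <- precursor_mz - 12
  if (hi <= lo) return(numeric(0))
  k <- sample(cfg$fragments_per_level[1L]:cfg$fragments_per_level[2L], 1L)
  sort(stats::runif(k, lo, hi))
}

sim_fragment_scan_peaks <- function(frag_mz, frag_base_int, precursor_mz,
                                    precursor_int, energy, cfg) {
  if (!length(frag_mz)) frag_mz <- numeric(0)
  # energy modulates the fragment/precursor balance: high energy depletes
  # the residual precursor and boosts fragments
  e_scale <- min(1, energy / 60)
  fint <- frag_base_int * (0.3 + 0.7 * e_scale) *
    stats::runif(length(frag_mz), 0.6, 1.4)
  resid <- precursor_int * max(0.02, 1 - e_scale) * stats::runif(1L, 0.5, 1)
  nn <- sample(cfg$noise_peaks_per_scan[1L]:cfg$noise_peaks_per_scan[2L], 1L)
  noise_mz <- stats::runif(nn, 50, precursor_mz)
  noise_int <- stats::rlnorm(nn, cfg$noise_intensity_meanlog - 2,
                             cfg$noise_intensity_sdlog)
  bg <- cfg$background_ions[cfg$background_ions$center_mz < precursor_mz, ,
                            drop = FALSE]
  mz <- c(jitter_mz(frag_mz, cfg$mz_jitter_ppm), precursor_mz, noise_mz,
          bg$center_mz)
  int <- c(fint, resid, noise_int,
           bg$intensity * stats::runif(nrow(bg), 0.05, 0.2))
  list(mz = mz, intensity = int)
}

#' Simulate one pooled-well flow-injection MSn acquisition
#'
#' Generates the scan list of a single injection under the data-dependent
#' MSn schema described in [sim_config()], together with the ground truth
#' of every (compound, adduct) tree emitted. Use `set.seed()` (or
#' [simulate_plate()], which seeds per injection) for reproducible output.
#'
#' @param cfg a [sim_config()].
#' @param compounds compound table rows pooled in this well (requires
#'   `name`, `inchikey`, `monoisotopic_mass`, `unique_sample_id`).
#' @param polarity `"positive"` or `"negative"`.
#' @param adducts adduct definition table ([default_adducts()]).
#' @return list with `scans` (list of [msn_scan()]) and `truth`
#'   (data.frame: one row per emitted compound-adduct tree, with
#'   `expected_mz`, `ms1_intensity`, `chimeric`).
#' @export
simulate_well <- function(cfg, compounds, polarity = "positive",
                          adducts = default_adducts()) {
  stopifnot(inherits(cfg, "sim_config"), nrow(compounds) > 0)
  polarity <- match.arg(polarity, c("positive", "negative"))
  adducts <- adducts[adducts$polarity == polarity, , drop = FALSE]
  probs <- cfg$adduct_probabilities[adducts$name]
  probs[is.na(probs)] <- 0

  # draw the well's ion population
  ions <- list()
  for (ci in seq_len(nrow(compounds))) {
    for (ai in seq_len(nrow(adducts))) {
      if (stats::runif(1L) > probs[ai]) next
      mz0 <- expected_ion_mz(compounds$monoisotopic_mass[ci],
                             adducts[ai, , drop = FALSE])
      if (mz0 < cfg$ms1_mz_range[1L] || mz0 > cfg$ms1_mz_range[2L]) next
      ions[[length(ions) + 1L]] <- list(
        compound = ci, adduct = adducts$name[ai],
        mz = mz0,
        obs_mz = jitter_mz(mz0, cfg$mz_jitter_ppm),
        intensity = stats::rlnorm(1L, cfg$ion_intensity_meanlog,
                                  cfg$ion_intensity_sdlog),
        chimeric = stats::runif(1L) < cfg$chimera_rate,
        iso1 = stats::runif(1L, 0.05, 0.30),
        iso2 = stats::runif(1L, 0.00, 0.10),
        assisted = sample(cfg$assisted_energies, 1L),
        frag_mz = numeric(0), frag_int = numeric(0), triggers = 0L)
    }
  }

  gate_ms2 <- cfg$min_intensity_ms2[[polarity]]
  gate_msn <- cfg$min_intensity_msn[[polarity]]
  for (k in seq_along(ions)) {
    ions[[k]]$frag_mz <- draw_fragments(ions[[k]]$mz, cfg)
    nf <- length(ions[[k]]$frag_mz)
    ions[[k]]$frag_int <- ions[[k]]$intensity *
      stats::runif(nf, 0.02, 0.6)
  }

  scans <- list()
  scan_no <- 0L
  rt <- 0.3
  emit <- function(ms_level, mz, int, chain) {
    scan_no <<- scan_no + 1L
    rt <<- rt + 0.004
    scans[[length(scans) + 1L]] <<- msn_scan(
      scan_number = scan_no, ms_level = ms_level, polarity = polarity,
      retention_time = rt, mz = mz, intensity = int,
      precursor_chain = chain)
    scan_no
  }

  ms1_peaks <- function() {
    mz <- numeric(0); int <- numeric(0)
    for (io in ions) {
      mz <- c(mz, io$obs_mz, io$obs_mz + 1.00335, io$obs_mz + 2 * 1.00335)
      cyc <- stats::runif(1L, 0.85, 1.15)  # shot-to-shot variation
      int <- c(int, io$intensity * cyc, io$intensity * cyc * io$iso1,
               io$intensity * cyc * io$iso2)
      if (io$chimeric) {
        off <- sample(c(-1, 1), 1L) * stats::runif(1L, 0.15, 0.45)
        mz <- c(mz, io$obs_mz + off)
        int <- c(int, io$intensity * cyc * stats::runif(1L, 0.6, 1.4))
      }
    }
    nn <- sample(cfg$noise_peaks_per_scan[1L]:cfg$noise_peaks_per_scan[2L], 1L)
    mz <- c(mz, stats::runif(nn, cfg$ms1_mz_range[1L], cfg$ms1_mz_range[2L]),
            cfg$background_ions$center_mz)
    int <- c(int, stats::rlnorm(nn, cfg$noise_intensity_meanlog,
                                cfg$noise_intensity_sdlog),
             cfg$background_ions$intensity *
               stats::runif(nrow(cfg$background_ions), 0.8, 1.2))
    list(mz = mz, intensity = int)
  }

  # deeper stages (MS3..MS5) for one precursor tree, triggered once per tree
  emit_deeper <- function(io, ms2_chain, ms2_assisted_peaks) {
    if (cfg$max_ms_level < 3L) return(invisible())
    sel <- which(ms2_assisted_peaks$mz >= cfg$msn_min_mz &
                   ms2_assisted_peaks$mz < io$obs_mz - 1 &
                   ms2_assisted_peaks$intensity >= gate_msn)
    sel <- sel[order(-ms2_assisted_peaks$intensity[sel])]
    sel <- utils::head(sel, cfg$topn_ms3)
    for (s3 in sel) {
      f3_mz <- ms2_assisted_peaks$mz[s3]
      f3_int <- ms2_assisted_peaks$intensity[s3]
      sub3_mz <- draw_fragments(f3_mz, cfg)
      sub3_int <- f3_int * stats::runif(length(sub3_mz), 0.05, 0.8)
      ms3_peaks_40 <- NULL
      for (e3 in cfg$energies_msn) {
        pk <- sim_fragment_scan_peaks(sub3_mz, sub3_int, f3_mz, f3_int, e3, cfg)
        chain3 <- rbind(ms2_chain, precursor_step(f3_mz, 2, e3))
        emit(3L, pk$mz, pk$intensity, chain3)
        if (e3 == 40) ms3_peaks_40 <- pk
      }
      if (cfg$max_ms_level < 4L || is.null(ms3_peaks_40)) next
      sel4 <- which(ms3_peaks_40$mz >= cfg$msn_min_mz &
                      ms3_peaks_40$mz < f3_mz - 1 &
                      ms3_peaks_40$intensity >= gate_msn)
      sel4 <- sel4[order(-ms3_peaks_40$intensity[sel4])]
      sel4 <- utils::head(sel4, cfg$topn_ms4)
      chain3_40 <- rbind(ms2_chain, precursor_step(f3_mz, 2, 40))
      for (s4 in sel4) {
        f4_mz <- ms3_peaks_40$mz[s4]
        f4_int <- ms3_peaks_40$intensity[s4]
        sub4_mz <- draw_fragments(f4_mz, cfg)
        sub4_int <- f4_int * stats::runif(length(sub4_mz), 0.05, 0.8)
        ms4_peaks_40 <- NULL
        for (e4 in cfg$energies_msn) {
          pk <- sim_fragment_scan_peaks(sub4_mz, sub4_int, f4_mz, f4_int, e4, cfg)
          chain4 <- rbind(chain3_40, precursor_step(f4_mz, 2.2, e4))
          emit(4L, pk$mz, pk$intensity, chain4)
          if (e4 == 40) ms4_peaks_40 <- pk
        }
        if (cfg$max_ms_level < 5L || is.null(ms4_peaks_40)) next
        sel5 <- which(ms4_peaks_40$mz >= cfg$ms5_min_mz &
                        ms4_peaks_40$mz < f4_mz - 1 &
                        ms4_peaks_40$intensity >= gate_msn)
        sel5 <- sel5[order(-ms4_peaks_40$intensity[sel5])]
        sel5 <- utils::head(sel5, cfg$topn_ms5)
        chain4_40 <- rbind(chain3_40, precursor_step(f4_mz, 2.2, 40))
        for (s5 in sel5) {
          f5_mz <- ms4_peaks_40$mz[s5]
          f5_int <- ms4_peaks_40$intensity[s5]
          sub5_mz <- draw_fragments(f5_mz, cfg)
          sub5_int <- f5_int * stats::runif(length(sub5_mz), 0.05, 0.8)
          for (e5 in cfg$energies_ms5) {
            pk <- sim_fragment_scan_peaks(sub5_mz, sub5_int, f5_mz, f5_int,
                                          e5, cfg)
            chain5 <- rbind(chain4_40, precursor_step(f5_mz, 3, e5))
            emit(5L, pk$mz, pk$intensity, chain5)
          }
        }
      }
    }
  }

  # DDA loop: MS1 survey + top-N selection until every eligible precursor
  # has been triggered repeat_triggers times (dynamic exclusion)
  eligible <- function() {
    vapply(ions, function(io) {
      io$intensity >= gate_ms2 && io$triggers < cfg$repeat_triggers
    }, logical(1L))
  }
  max_cycles <- ceiling(length(ions) * cfg$repeat_triggers /
                          cfg$topn_ms2) + 2L
  deep_done <- logical(length(ions))
  if (!length(ions) || !any(eligible())) {
    # nothing ionizes above the gates: the survey scans still happen
    for (i in 1:2) { pk1 <- ms1_peaks(); emit(1L, pk1$mz, pk1$intensity, NULL) }
  }
  cycle <- 0L
  while (any(eligible()) && cycle < max_cycles) {
    cycle <- cycle + 1L
    pk1 <- ms1_peaks()
    emit(1L, pk1$mz, pk1$intensity, NULL)
    elig <- which(eligible())
    sel <- elig[order(-vapply(ions[elig], `[[`, numeric(1L), "intensity"))]
    sel <- utils::head(sel, cfg$topn_ms2)
    for (k in sel) {
      io <- ions[[k]]
      ions[[k]]$triggers <- io$triggers + 1L
      energies <- cfg$energies_ms2
      energies[is.na(energies)] <- io$assisted
      assisted_peaks <- NULL
      for (e2 in energies) {
        pk <- sim_fragment_scan_peaks(io$frag_mz, io$frag_int, io$obs_mz,
                                      io$intensity * 0.1, e2, cfg)
        chain2 <- precursor_step(io$obs_mz, cfg$isolation_width_ms2, e2)
        emit(2L, pk$mz, pk$intensity, chain2)
        if (e2 == io$assisted) assisted_peaks <- pk
      }
      if (!deep_done[k] && !is.null(assisted_peaks)) {
        deep_done[k] <- TRUE
        emit_deeper(io, precursor_step(io$obs_mz, cfg$isolation_width_ms2,
                                       io$assisted),
                    assisted_peaks)
      }
    }
  }

  emitted <- vapply(ions, function(io) io$triggers > 0L, logical(1L))
  truth <- if (any(emitted)) {
    do.call(rbind, lapply(ions[emitted], function(io) {
      data.frame(
        name = compounds$name[io$compound],
        inchikey = compounds$inchikey[io$compound],
        unique_sample_id = compounds$unique_sample_id[io$compound],
        adduct_name = io$adduct,
        expected_mz = io$mz,
        observed_mz = io$obs_mz,
        ms1_intensity = io$intensity,
        chimeric = io$chimeric,
        polarity = polarity,
        stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(name = character(0), inchikey = character(0),
               unique_sample_id = character(0), adduct_name = character(0),
               expected_mz = numeric(0), observed_mz = numeric(0),
               ms1_intensity = numeric(0), chimeric = logical(0),
               polarity = character(0), stringsAsFactors = FALSE)
  }
  list(scans = scans, truth = truth)
}

#' Simulate a full plate set against an acquisition sequence
#'
#' Runs [simulate_well()] for every row of an acquisition sequence and
#' writes one scan file per injection, named after the sequence row (so
#' each file name contains its well's unique sample identifier), plus a
#' combined ground-truth JSON.
#'
#' @param cfg a [sim_config()]; per-injection seeds are derived from
#'   `cfg$seed` and the injection index.
#' @param metadata curated compound table (with `unique_sample_id`,
#'   `monoisotopic_mass`, `inchikey`, `name`).
#' @param sequence acquisition sequence from [generate_sequence()].
#' @param dir output directory (created if needed).
#' @param formats scan formats to write: subset of `"scanjson"`, `"mzml"`.
#' @param adducts adduct table used for ion generation.
#' @return list with `files` (paths of the primary scanjson files), `truth`
#'   (combined ground-truth data.frame, also written as
#'   `ground_truth.json`).
#' @export
simulate_plate <- function(cfg, metadata, sequence, dir,
                           formats = "scanjson",
                           adducts = default_adducts()) {
  stopifnot(inherits(cfg, "sim_config"),
            all(formats %in% c("scanjson", "mzml")),
            "scanjson" %in% formats)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  missing_wells <- setdiff(sequence$unique_sample_id, metadata$unique_sample_id)
  if (length(missing_wells)) {
    stop("sequence references wells absent from metadata: ",
         paste(missing_wells, collapse = ", "))
  }
  files <- character(0)
  truths <- list()
  for (i in seq_len(nrow(sequence))) {
    row <- sequence[i, ]
    set.seed((cfg$seed * 10007L + row$injection_index) %% .Machine$integer.max)
    compounds <- metadata[metadata$unique_sample_id == row$unique_sample_id, ,
                          drop = FALSE]
    sim <- simulate_well(cfg, compounds, polarity = row$polarity,
                         adducts = adducts)
    path <- file.path(dir, paste0(row$filename, ".scanjson"))
    write_scans(sim$scans, path, format = "scanjson")
    if ("mzml" %in% formats && length(sim$scans)) {
      write_scans(sim$scans, file.path(dir, paste0(row$filename, ".mzML")),
                  format = "mzml")
    }
    files <- c(files, path)
    if (nrow(sim$truth)) {
      sim$truth$filename <- basename(path)
      truths[[length(truths) + 1L]] <- sim$truth
    }
  }
  truth <- if (length(truths)) do.call(rbind, truths) else NULL
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = I(17))
  list(files = files, truth = truth)
}

#' Generate a synthetic pooled-compound metadata table
#'
#' Builds a curated-style compound table for simulation tests without any
#' structure handling: compounds get synthetic names, distinct
#' synthetic InChIKeys (valid format, labelled `SYNTH`), and monoisotopic
#' masses drawn uniformly in a configurable range with a minimum within-well
#' separation so pooled compounds stay mass-resolvable.
#'
#' @param n_wells number of wells per plate.
#' @param compounds_per_well pooled compounds per well.
#' @param n_plates number of plates.
#' @param library_code library label used in sample identifiers.
#' @param mass_range monoisotopic mass range (Da).
#' @param min_mass_gap minimum mass separation within a well (Da).
#' @return data.frame usable as curated metadata for [simulate_plate()].
#' @export
synthetic_compound_table <- function(n_wells = 4L, compounds_per_well = 10L,
                                     n_plates = 1L, library_code = "SIMLIB",
                                     mass_range = c(150, 750),
                                     min_mass_gap = 1.5) {
  rows <- list()
  idx <- 0L
  for (p in seq_len(n_plates)) {
    for (w in seq_len(n_wells)) {
      well <- sprintf("%s%d", LETTERS[(w - 1L) %/% 12L + 1L],
                      (w - 1L) %% 12L + 1L)
      masses <- numeric(0)
      while (length(masses) < compounds_per_well) {
        m <- stats::runif(1L, mass_range[1L], mass_range[2L])
        if (!length(masses) || min(abs(masses - m)) >= min_mass_gap) {
          masses <- c(masses, m)
        }
      }
      for (m in masses) {
        idx <- idx + 1L
        key <- paste0(paste(sample(LETTERS, 14L, replace = TRUE),
                            collapse = ""), "-",
                      paste(sample(LETTERS, 10L, replace = TRUE),
                            collapse = ""), "-N")
        rows[[idx]] <- data.frame(
          name = sprintf("SYNTH_%04d", idx),
          inchikey = key,
          monoisotopic_mass = m,
          library_code = library_code,
          plate = as.character(p),
          well = well,
          stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, rows)
  assign_sample_ids(df)
}
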