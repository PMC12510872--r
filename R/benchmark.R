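#' End-to-end simulation recovery benchmark
#'
#' Validation harness for the whole pipeline: generates a pooled-compound
#' plate set, simulates the flow-injection MSn acquisition for every
#' sequence row, runs [build_library()] on the simulated files, and scores
#' the result against the simulator's ground truth. Two quantities are
#' reported: the percentage of emitted (compound, adduct, polarity) trees
#' that were annotated and exported, and the number of cross-well leaks
#' (exported entries attributed to a compound that was not pooled in the
#' well the source file came from; the sample-ID constraint makes this
#' zero by construction unless annotation is broken).
#'
#' @param seed integer seed driving metadata generation and acquisition.
#' @param n_plates,wells_per_plate,compounds_per_well plate layout.
#' @param dir working directory for simulated scans and library output.
#' @param cfg optional [sim_config()]; its seed is overridden by `seed`.
#' @return list with `recovery_pct`, `leakage_count`, `n_truth_pairs`,
#'   `n_recovered_pairs`, `n_entries`, and the pipeline `report`.
#' @export
simulation_recovery <- function(seed = 1L, n_plates = 2L,
                                wells_per_plate = 4L,
                                compounds_per_well = 10L,
                                dir = tempdir(), cfg = NULL) {
  set.seed(seed)
  meta <- synthetic_compound_table(n_wells = wells_per_plate,
                                   compounds_per_well = compounds_per_well,
                                   n_plates = n_plates)
  seqd <- generate_sequence(unique_wells(meta), "2026-01-01", "FIMSN")
  if (is.null(cfg)) cfg <- sim_config(seed = seed)
  cfg$seed <- as.integer(seed)
  scan_dir <- file.path(dir, "scans")
  sim <- simulate_plate(cfg, meta, seqd, scan_dir)
  res <- build_library(meta, sim$files, file.path(dir, "library"))

  entries <- c(res$entries$positive, res$entries$negative)
  exported <- unique(data.frame(
    inchikey = vapply(entries, `[[`, character(1L), "inchikey"),
    adduct_name = vapply(entries, `[[`, character(1L), "adduct_name"),
    polarity = vapply(entries, `[[`, character(1L), "polarity"),
    source_file = vapply(entries, `[[`, character(1L), "source_file"),
    stringsAsFactors = FALSE))

  truth_key <- unique(paste(sim$truth$inchikey, sim$truth$adduct_name,
                            sim$truth$polarity))
  got_key <- unique(paste(exported$inchikey, exported$adduct_name,
                          exported$polarity))
  recovered <- sum(truth_key %in% got_key)

  # cross-well leakage: an exported compound must be pooled in the well
  # its source file was acquired from
  leaks <- 0L
  for (f in unique(exported$source_file)) {
    allowed <- compounds_for_file(f, meta)$inchikey
    leaks <- leaks + sum(!exported$inchikey[exported$source_file == f] %in%
                           allowed)
  }

  list(recovery_pct = 100 * recovered / length(truth_key),
       leakage_count = leaks,
       n_truth_pairs = length(truth_key),
       n_recovered_pairs = recovered,
       n_entries = length(entries),
       report = res$report)
}
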