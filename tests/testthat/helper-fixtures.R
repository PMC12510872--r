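# Shared fixtures and independent oracles for the test suite.

make_chain <- function(mzs, energies, widths = NULL) {
  if (is.null(widths)) widths <- rep(1.2, length(mzs))
  data.frame(precursor_mz = mzs, isolation_width = widths,
             collision_energy = energies)
}

make_scan <- function(mz, intensity, ms_level = 2L, scan_number = 1L,
                      polarity = "positive", rt = 0.5, chain = NULL,
                      precursor = 300, energy = 20, width = 1.2) {
  if (is.null(chain) && ms_level > 1L) {
    stopifnot(ms_level == 2L)
    chain <- make_chain(precursor, energy, width)
  }
  msn_scan(scan_number = scan_number, ms_level = ms_level,
           polarity = polarity, retention_time = rt,
           mz = mz, intensity = intensity, precursor_chain = chain)
}

random_spectrum <- function(n = NULL, mz_range = c(50, 500)) {
  if (is.null(n)) n <- sample(1:6, 1L)
  list(mz = sort(runif(n, mz_range[1L], mz_range[2L])),
       intensity = runif(n, 1, 100))
}

random_scan <- function(scan_number = 1L, n_peaks = NULL) {
  if (is.null(n_peaks)) n_peaks <- sample(3:40, 1L)
  mz <- sort(runif(n_peaks, 50, 800))
  # include occasional peaks inside the background windows
  if (runif(1) < 0.5) mz <- sort(c(mz, 149.72 + runif(1, -0.014, 0.014)))
  make_scan(mz, rlnorm(length(mz), log(1e4), 1.5),
            scan_number = scan_number, precursor = 810)
}

# A realistic query/reference pair for pairing checks: the two spectra
# share a jittered subset of peaks (mass error below the match tolerance)
# plus independent extras, so most peaks have zero or one match candidate
# and occasional close doublets create genuine assignment ambiguity.
random_match_pair <- function(mz_tol = 0.02) {
  na <- sample(1:6, 1L); nb <- sample(1:6, 1L)
  a <- list(mz = sort(runif(na, 50, 500)), intensity = runif(na, 1, 100))
  k <- sample(0:min(na, nb), 1L)
  shared <- if (k > 0) sample(a$mz, k) + runif(k, -mz_tol / 2, mz_tol / 2)
            else numeric(0)
  extra <- runif(nb - k, 50, 500)
  ord <- order(c(shared, extra))
  b <- list(mz = c(shared, extra)[ord], intensity = runif(nb, 1, 100))
  list(a = a, b = b)
}

random_entry <- function(i, n_peaks = NULL) {
  if (is.null(n_peaks)) n_peaks <- sample(2:30, 1L)
  spec_type <- sample(SPEC_TYPES_TEST, 1L)
  energies <- switch(spec_type,
                     SAME_ENERGY = sample(c(20, 40, 60), 1L),
                     sort(sample(c(20, 40, 45, 60, 75), sample(1:3, 1L))))
  library_entry(
    name = sprintf("CMP%04d", i),
    adduct_name = sample(c("[M+H]+", "[M+Na]+", "[M-H]-", NA), 1L),
    precursor_mz = runif(1, 120, 900),
    mz = sort(runif(n_peaks, 50, 900)),
    intensity = runif(n_peaks, 1, 1e6),
    ms_level = sample(2:5, 1L),
    spec_type = spec_type,
    collision_energies = energies,
    polarity = sample(c("positive", "negative"), 1L),
    formula = sample(c("C6H12O6", "C10H14N2", NA), 1L),
    smiles = sample(c("CCO", "c1ccccc1C", NA), 1L),
    inchikey = paste0(paste(sample(LETTERS, 14, TRUE), collapse = ""), "-",
                      paste(sample(LETTERS, 10, TRUE), collapse = ""), "-N"),
    precursor_purity_pct = sample(c(runif(1, 0, 100), NA), 1L),
    chimeric_flag = sample(c(TRUE, FALSE), 1L),
    source_file = "run_001.scanjson",
    scan_numbers = sort(sample(1:500, sample(1:4, 1L)))
  )
}

SPEC_TYPES_TEST <- c("SINGLE_BEST_SCAN", "SAME_ENERGY", "ALL_ENERGIES",
                     "ALL_MSN_TO_PSEUDO_MS2")

expect_entries_equal <- function(got, want) {
  expect_equal(length(got), length(want))
  fields <- c("name", "adduct_name", "precursor_mz", "ms_level", "spec_type",
              "collision_energies", "polarity", "formula", "smiles", "inchi",
              "inchikey", "precursor_purity_pct", "chimeric_flag",
              "source_file", "scan_numbers", "mz", "intensity")
  for (k in seq_along(want)) {
    for (f in fields) {
      expect_equal(got[[k]][[f]], want[[k]][[f]], tolerance = 0,
                   label = sprintf("entry %d field %s (read back)", k, f),
                   expected.label = "written value")
    }
  }
}

# Independent oracle: optimal one-to-one peak assignment by exhaustive
# recursion (feasible for <= 6 peaks), maximizing the weighted dot product.
brute_force_cosine <- function(a, b, mz_tol = 0.005, mz_power = 0,
                               intensity_power = 0.5) {
  wa <- a$mz^mz_power * a$intensity^intensity_power
  wb <- b$mz^mz_power * b$intensity^intensity_power
  na <- length(a$mz); nb <- length(b$mz)
  best <- 0
  recurse <- function(i, used_b, acc) {
    if (i > na) { best <<- max(best, acc); return(invisible()) }
    recurse(i + 1L, used_b, acc)  # leave peak i unmatched
    for (j in seq_len(nb)) {
      if (!used_b[j] && abs(a$mz[i] - b$mz[j]) <= mz_tol) {
        used_b[j] <- TRUE
        recurse(i + 1L, used_b, acc + wa[i] * wb[j])
        used_b[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(nb), 0)
  denom <- sum(wa^2) * sum(wb^2)
  if (denom > 0) best^2 / denom else 0
}

# Independent oracle: pool all peaks of the supplied spectra (base-peak
# normalized) and re-bin in one pass, sorted single linkage.
union_rebin <- function(spectra, mz_tol = 0.005) {
  mz <- numeric(0); int <- numeric(0)
  for (sp in spectra) {
    s_int <- sp$intensity
    if (length(s_int) && max(s_int) > 0) s_int <- s_int / max(s_int) * 100
    mz <- c(mz, sp$mz); int <- c(int, s_int)
  }
  if (!length(mz)) return(list(mz = numeric(0), intensity = numeric(0)))
  ord <- order(mz); mz <- mz[ord]; int <- int[ord]
  grp <- cumsum(c(1, as.integer(diff(mz) > mz_tol)))
  out_mz <- out_int <- numeric(0)
  for (g in unique(grp)) {
    ix <- which(grp == g)
    w <- int[ix]
    out_mz <- c(out_mz, if (sum(w) > 0) sum(mz[ix] * w) / sum(w) else mean(mz[ix]))
    out_int <- c(out_int, max(w))
  }
  list(mz = out_mz, intensity = out_int)
}

tree_depth_t <- function(node) {
  if (!length(node$children)) return(node$ms_level)
  max(vapply(node$children, tree_depth_t, numeric(1)))
}

tree_scan_count_t <- function(node) {
  length(node$scans) + sum(vapply(node$children, tree_scan_count_t,
                                  integer(1)))
}

# compact structural signature of a tree for order-invariance comparisons
tree_signature <- function(node) {
  scans <- sort(vapply(node$scans, `[[`, integer(1L), "scan_number"))
  kid_sigs <- vapply(node$children, tree_signature, character(1L))
  sprintf("L%d[%.4f]{%s}(%s)", node$ms_level, node$precursor_mz,
          paste(scans, collapse = ","), paste(sort(kid_sigs), collapse = ";"))
}

# small curated-style metadata table for annotation tests (no chemistry
# toolkit needed: masses and keys are synthetic)
tiny_metadata <- function() {
  df <- data.frame(
    name = c("alpha", "beta", "gamma", "delta"),
    inchikey = c("AAAAAAAAAAAAAA-AAAAAAAAAA-N", "BBBBBBBBBBBBBB-BBBBBBBBBB-N",
                 "CCCCCCCCCCCCCC-CCCCCCCCCC-N", "DDDDDDDDDDDDDD-DDDDDDDDDD-N"),
    monoisotopic_mass = c(180.0634, 255.0899, 310.1412, 444.1729),
    library_code = "TESTLIB",
    plate = c("1", "1", "2", "2"),
    well = c("A1", "A2", "A1", "A2"),
    stringsAsFactors = FALSE)
  assign_sample_ids(df)
}
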