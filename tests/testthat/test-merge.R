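# Consensus building: peak binning and the three merge levels.

test_that("binning identical spectra returns the normalized input", {
  sp <- list(mz = c(100, 200, 300), intensity = c(10, 40, 20))
  out <- bin_peaks(list(sp, sp))
  expect_equal(out$mz, sp$mz)
  expect_equal(out$intensity, c(25, 100, 50))
})

test_that("peaks within tolerance merge at the intensity-weighted mean", {
  a <- list(mz = 100.000, intensity = 10)
  b <- list(mz = 100.004, intensity = 30)
  out <- bin_peaks(list(a, b), mz_tol = 0.01)
  expect_length(out$mz, 1L)
  # both spectra normalize to 100, so the weighted mean is the midpoint
  expect_equal(out$mz, (100.000 + 100.004) / 2)
  expect_equal(out$intensity, 100)
  # disjoint m/z sets union additively
  disj <- bin_peaks(list(list(mz = c(100, 200), intensity = c(1, 2)),
                         list(mz = c(300, 400), intensity = c(3, 4))),
                    mz_tol = 0.01)
  expect_length(disj$mz, 4L)
})

test_that("merged peaks stay inside member bounds at intensity <= 100", {
  set.seed(51)
  for (rep in 1:20) {
    spectra <- lapply(1:3, function(i) random_spectrum(sample(2:8, 1)))
    out <- bin_peaks(spectra, mz_tol = 0.5)
    all_mz <- unlist(lapply(spectra, `[[`, "mz"))
    expect_true(all(out$mz >= min(all_mz) & out$mz <= max(all_mz)))
    expect_true(all(out$intensity <= 100 + 1e-12))
    expect_false(is.unsorted(out$mz))
    # order invariance
    out2 <- bin_peaks(rev(spectra), mz_tol = 0.5)
    expect_equal(out2, out)
  }
})

node_with_scans <- function(...) {
  build_trees(list(...))[[1]]
}

test_that("same-energy consensus requires repeat triggers", {
  s1 <- make_scan(c(100, 150), c(50, 100), scan_number = 1L, energy = 40)
  s2 <- make_scan(c(100.002, 150.001), c(60, 90), scan_number = 2L,
                  energy = 40)
  s3 <- make_scan(c(100, 150), c(40, 80), scan_number = 3L, energy = 40)
  node <- node_with_scans(s1, s2, s3)
  cons <- merge_same_energy(node, 40)
  expect_equal(attr(cons, "energies"), 40)
  expect_equal(attr(cons, "scan_numbers"), 1:3)
  expect_length(cons$mz, 2L)
  expect_lte(length(cons$mz), sum(lengths(list(s1$mz, s2$mz, s3$mz))))
  # single trigger: absent, caller falls back to the best scan
  single <- node_with_scans(s1)
  expect_null(merge_same_energy(single, 40))
  expect_equal(select_best_scan(single, 40)$scan_number, 1L)
})

test_that("all-energies merge lists every energy used", {
  mk <- function(sn, e) make_scan(c(100, 150 + e / 100), c(50, 100),
                                  scan_number = sn, energy = e)
  node <- node_with_scans(mk(1L, 20), mk(2L, 60), mk(3L, 45))
  merged <- merge_all_energies(node)
  expect_equal(attr(merged, "energies"), c(20, 45, 60))
  expect_equal(attr(merged, "scan_numbers"), 1:3)
  # single energy present: merge equals that spectrum, normalized
  node1 <- node_with_scans(mk(1L, 20))
  m1 <- merge_all_energies(node1)
  expect_equal(m1$mz, c(100, 150.2))
  expect_equal(m1$intensity, c(50, 100))
})

test_that("a peak present at all energies keeps the max normalized height", {
  mk <- function(sn, e, ints) make_scan(c(100, 200), ints, scan_number = sn,
                                        energy = e)
  node <- node_with_scans(mk(1L, 20, c(30, 100)), mk(2L, 60, c(100, 20)))
  merged <- merge_all_energies(node)
  expect_equal(merged$intensity, c(100, 100))
})

test_that("pseudo-MS2 of a degenerate tree equals the trimmed root merge", {
  s1 <- make_scan(c(100, 150, 301.139), c(50, 100, 20), scan_number = 1L,
                  precursor = 301.14, energy = 20)
  root <- node_with_scans(s1)
  ps <- build_pseudo_ms2(root)
  direct <- remove_precursor_peaks(merge_all_energies(root),
                                   root$precursor_mz)
  expect_equal(ps$mz, direct$mz)
  expect_equal(ps$intensity, rep(100, 2) * c(0.5, 1))
})

test_that("pseudo-MS2 unions fragments from deeper stages", {
  ms2 <- make_scan(c(255.1, 100), c(100, 50), scan_number = 1L,
                   precursor = 301.14, energy = 20)
  ms3 <- make_scan(c(91.05, 120), c(80, 40), ms_level = 3L, scan_number = 2L,
                   chain = make_chain(c(301.14, 255.1), c(20, 40), c(1.2, 2)))
  root <- node_with_scans(ms2, ms3)
  ps <- build_pseudo_ms2(root)
  expect_true(any(abs(ps$mz - 91.05) < 1e-6))
  root_only <- remove_precursor_peaks(merge_all_energies(root),
                                      root$precursor_mz)
  expect_gte(length(ps$mz), length(root_only$mz))
})

test_that("pseudo-MS2 equals the brute-force union of subtree spectra", {
  set.seed(52)
  meta <- synthetic_compound_table(n_wells = 1, compounds_per_well = 2)
  sim <- simulate_well(sim_config(seed = 52, max_ms_level = 4), meta,
                       "positive")
  forest <- build_trees(Filter(function(s) s$ms_level >= 2L, sim$scans))
  roots <- Filter(function(r) r$ms_level == 2L && !r$orphan, forest)
  for (root in roots[seq_len(min(3, length(roots)))]) {
    ps <- build_pseudo_ms2(root)
    parts <- list()
    for (node in msnforest:::tree_nodes(root)) {
      sp <- merge_all_energies(node)
      if (is.null(sp)) next
      sp <- remove_precursor_peaks(sp, node$precursor_mz)
      if (length(sp$mz)) parts[[length(parts) + 1L]] <- sp
    }
    oracle <- union_rebin(parts, mz_tol = 0.005)
    expect_equal(length(ps$mz), length(oracle$mz))
    expect_true(all(abs(ps$mz - oracle$mz) <= 0.005))
  }
})
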