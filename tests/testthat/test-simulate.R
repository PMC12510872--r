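# Synthetic DDA acquisition: determinism, schema fidelity, ground truth.

test_that("a fixed seed gives byte-identical scan files", {
  meta <- local({ set.seed(71); synthetic_compound_table(n_wells = 1,
                                                         compounds_per_well = 3) })
  seqd <- generate_sequence(unique_wells(meta), "2026-03-01", "FIMSN")[1, ]
  cfg <- sim_config(seed = 71, max_ms_level = 4)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- simulate_plate(cfg, meta, seqd, d1)$files
  f2 <- simulate_plate(cfg, meta, seqd, d2)$files
  expect_identical(readLines(f1), readLines(f2))
})

test_that("a clean single-compound run yields one annotatable tree per ion", {
  set.seed(72)
  meta <- synthetic_compound_table(n_wells = 1, compounds_per_well = 1)
  cfg <- sim_config(seed = 72, chimera_rate = 0,
                    adduct_probabilities = c("[M+H]+" = 1),
                    max_ms_level = 3)
  sim <- simulate_well(cfg, meta, "positive")
  expect_equal(nrow(sim$truth), 1L)
  expect_equal(sim$truth$adduct_name, "[M+H]+")
  h <- default_adducts()
  expect_equal(sim$truth$expected_mz,
               expected_ion_mz(meta$monoisotopic_mass,
                               h[h$name == "[M+H]+", ]))
  filtered <- lapply(sim$scans, noise_filter)
  forest <- build_trees(Filter(function(s) s$ms_level >= 2L, filtered))
  roots <- Filter(function(r) r$ms_level == 2L && !r$orphan, forest)
  expect_equal(length(roots), 1L)
  ann <- annotate_forest(roots, meta, polarity = "positive")
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$inchikey, meta$inchikey)
})

test_that("chimera injection degrades purity below 100 and flags it", {
  set.seed(73)
  meta <- synthetic_compound_table(n_wells = 1, compounds_per_well = 3)
  cfg <- sim_config(seed = 73, chimera_rate = 1, max_ms_level = 2)
  sim <- simulate_well(cfg, meta, "positive")
  expect_true(all(sim$truth$chimeric))
  ms1_idx <- which(vapply(sim$scans, `[[`, integer(1), "ms_level") == 1L)
  ms2 <- Filter(function(s) s$ms_level == 2L, sim$scans)
  for (sc in ms2[seq_len(min(6, length(ms2)))]) {
    before <- sim$scans[[max(ms1_idx[ms1_idx < sc$scan_number])]]
    res <- precursor_purity(before, NULL,
                            precursor_mz = sc$precursor_chain$precursor_mz[1],
                            isolation_width = sc$precursor_chain$isolation_width[1])
    expect_lt(res$purity_pct, 100)
    expect_true(res$chimeric_flag)
  }
})

test_that("no simulated fragment exceeds its precursor m/z", {
  set.seed(74)
  meta <- synthetic_compound_table(n_wells = 1, compounds_per_well = 4)
  sim <- simulate_well(sim_config(seed = 74), meta, "positive")
  for (sc in sim$scans) {
    if (sc$ms_level < 2L) next
    prec <- sc$precursor_chain$precursor_mz[nrow(sc$precursor_chain)]
    expect_true(all(sc$mz <= prec * (1 + 1e-5)))
  }
  expect_true(all(vapply(sim$scans, function(s) !is.unsorted(s$mz),
                         logical(1))))
})

test_that("raising the noise level does not increase recovered compounds", {
  recovered <- function(noise_meanlog, seed) {
    set.seed(seed)
    meta <- synthetic_compound_table(n_wells = 1, compounds_per_well = 4)
    cfg <- sim_config(seed = seed, max_ms_level = 2,
                      noise_intensity_meanlog = noise_meanlog)
    sim <- simulate_well(cfg, meta, "positive")
    filtered <- lapply(sim$scans, noise_filter)
    forest <- build_trees(Filter(function(s) s$ms_level >= 2L, filtered))
    ann <- annotate_forest(forest, meta, polarity = "positive")
    length(unique(ann$inchikey))
  }
  lo <- vapply(1:5, function(s) recovered(log(4e3), s), numeric(1))
  hi <- vapply(1:5, function(s) recovered(log(4e5), s), numeric(1))
  expect_lte(mean(hi), mean(lo))
})

test_that("simulated plates write one named file per sequence row", {
  meta <- local({ set.seed(75); synthetic_compound_table(n_wells = 2,
                                                         compounds_per_well = 2) })
  seqd <- generate_sequence(unique_wells(meta), "2026-03-02", "FIMSN")
  d <- withr::local_tempdir()
  res <- simulate_plate(sim_config(seed = 75, max_ms_level = 2), meta, seqd, d)
  expect_length(res$files, 4L)
  for (i in seq_len(nrow(seqd))) {
    expect_true(grepl(seqd$unique_sample_id[i], basename(res$files[i]),
                      fixed = TRUE))
    expect_true(file.exists(res$files[i]))
  }
  expect_error(
    simulate_plate(sim_config(seed = 75),
                   meta[meta$unique_sample_id != seqd$unique_sample_id[1], ],
                   seqd, d),
    "absent from metadata")
})
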