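# Scan and library file round trips, and tolerant foreign-format reading.

test_that("scanjson write/read preserves scans exactly", {
  set.seed(21)
  meta <- synthetic_compound_table(n_wells = 1, compounds_per_well = 3)
  sim <- simulate_well(sim_config(seed = 21, max_ms_level = 4), meta,
                       "positive")
  path <- withr::local_tempfile(fileext = ".scanjson")
  write_scans(sim$scans, path)
  back <- read_scans(path)
  expect_equal(length(back), length(sim$scans))
  expect_equal(vapply(back, `[[`, integer(1), "ms_level"),
               vapply(sim$scans, `[[`, integer(1), "ms_level"))
  expect_identical(sum(vapply(back, `[[`, numeric(1), "tic")),
                   sum(vapply(sim$scans, `[[`, numeric(1), "tic")))
  for (k in seq_along(back)) {
    expect_identical(back[[k]]$mz, sim$scans[[k]]$mz)
    expect_identical(back[[k]]$noise_floor, sim$scans[[k]]$noise_floor)
    expect_equal(back[[k]]$precursor_chain, sim$scans[[k]]$precursor_chain)
  }
})

test_that("mzML write/read reconstructs full precursor chains", {
  set.seed(22)
  meta <- synthetic_compound_table(n_wells = 1, compounds_per_well = 2)
  sim <- simulate_well(sim_config(seed = 22), meta, "negative")
  path <- withr::local_tempfile(fileext = ".mzML")
  write_scans(sim$scans, path, format = "mzml")
  back <- read_scans(path)
  expect_equal(length(back), length(sim$scans))
  expect_equal(sum(vapply(back, `[[`, numeric(1), "tic")),
               sum(vapply(sim$scans, `[[`, numeric(1), "tic")))
  expect_true(all(vapply(back, `[[`, character(1), "polarity") == "negative"))
  for (k in seq_along(back)) {
    expect_equal(back[[k]]$precursor_chain, sim$scans[[k]]$precursor_chain,
                 tolerance = 1e-6)
    expect_equal(back[[k]]$mz, sim$scans[[k]]$mz, tolerance = 1e-9)
  }
})

test_that("scan fixtures with mixed content parse as specified", {
  s1 <- make_scan(c(100, 200), c(5, 10), ms_level = 1L, chain = NULL,
                  scan_number = 1L)
  s23 <- lapply(2:4, function(i) {
    make_scan(c(80, 120), c(3, 9), scan_number = i, precursor = 200.1)
  })
  path <- withr::local_tempfile(fileext = ".scanjson")
  write_scans(c(list(s1), s23), path)
  back <- read_scans(path)
  expect_equal(length(back), 4L)
  expect_equal(vapply(back, function(s) nrow(s$precursor_chain), integer(1)),
               c(0L, 1L, 1L, 1L))
  # empty scan list round-trips with a warning on read
  write_scans(list(), path)
  expect_warning(empty <- read_scans(path), "no scans")
  expect_length(empty, 0L)
})

test_that("files mixing polarities are rejected", {
  scans <- list(
    make_scan(100, 10, ms_level = 1L, chain = NULL, scan_number = 1L),
    make_scan(90, 5, scan_number = 2L, polarity = "negative"))
  path <- withr::local_tempfile(fileext = ".scanjson")
  write_scans(scans, path)
  expect_error(read_scans(path), "mixes polarities")
})

test_that("library write/read is the identity in all three formats", {
  set.seed(23)
  entries <- lapply(1:25, random_entry)
  for (fmt in c("mgf", "msp", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_library(entries, path)
    back <- read_library(path)
    expect_entries_equal(back, entries)
  }
})

test_that("foreign MGF with lower-case keys parses via the alias table", {
  path <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c(
    "BEGIN IONS",
    "pepmass=301.1402",
    "charge=1+",
    "title=foreign compound",
    "precursortype=[M+H]+",
    "inchiaux=AAAAAAAAAAAAAA-AAAAAAAAAA-N",
    "100.1 55",
    "200.2 99",
    "END IONS"), path)
  back <- read_library(path)
  expect_length(back, 1L)
  expect_equal(back[[1]]$precursor_mz, 301.1402)
  expect_equal(back[[1]]$name, "foreign compound")
  expect_equal(back[[1]]$adduct_name, "[M+H]+")
  expect_equal(back[[1]]$inchikey, "AAAAAAAAAAAAAA-AAAAAAAAAA-N")
  expect_equal(back[[1]]$mz, c(100.1, 200.2))
})

test_that("foreign MSP key variants parse via the alias table", {
  path <- withr::local_tempfile(fileext = ".msp")
  writeLines(c(
    "Name: nist style",
    "PRECURSORMZ: 180.05",
    "Precursor_type: [M-H]-",
    "Ion_mode: N",
    "Spectrum_type: MS2",
    "Num Peaks: 2",
    "80.0 10; 90.0 20"), path)
  back <- read_library(path)
  expect_length(back, 1L)
  expect_equal(back[[1]]$precursor_mz, 180.05)
  expect_equal(back[[1]]$polarity, "negative")
  expect_equal(back[[1]]$ms_level, 2L)
  expect_equal(back[[1]]$mz, c(80, 90))
})

test_that("records without peaks are skipped and counted", {
  entries <- list(random_entry(1))
  path <- withr::local_tempfile(fileext = ".mgf")
  write_library(entries, path)
  txt <- readLines(path)
  empty_rec <- c("BEGIN IONS", "PEPMASS=100.0", "END IONS", "")
  writeLines(c(txt, empty_rec), path)
  expect_warning(back <- read_library(path), "without peaks")
  expect_length(back, 1L)
  expect_equal(attr(back, "n_skipped"), 1L)
})

test_that("truncated library files fail naming the offending record", {
  mgf <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "PEPMASS=100.0", "50.0 1"), mgf)
  expect_error(read_library(mgf), "record 1")
  msp <- withr::local_tempfile(fileext = ".msp")
  writeLines(c("Name: cut off", "PrecursorMZ: 100.0", "Num Peaks: 5",
               "50.0 1"), msp)
  expect_error(read_library(msp), "record 1")
})

test_that("MSP peak count cross-checks the promised Num Peaks", {
  msp <- withr::local_tempfile(fileext = ".msp")
  writeLines(c("Name: a", "PrecursorMZ: 100.0", "Num Peaks: 1", "50.0 1", "",
               "Name: b", "PrecursorMZ: 200.0", "Num Peaks: 2",
               "60.0 1", "70.0 2"), msp)
  back <- read_library(msp)
  expect_length(back, 2L)
  expect_equal(back[[2]]$mz, c(60, 70))
})
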