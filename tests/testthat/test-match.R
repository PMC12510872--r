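# Weighted cosine matching, library search, overlap and Tanimoto.

test_that("precursor removal drops the precursor region", {
  sp <- list(mz = c(100, 295, 299.999, 300, 305), intensity = rep(1, 5))
  out <- remove_precursor_peaks(sp, 300, tol = 0.005)
  expect_equal(out$mz, c(100, 295))
  all_above <- remove_precursor_peaks(list(mz = c(400, 500),
                                           intensity = c(1, 2)), 300)
  expect_length(all_above$mz, 0L)
  windowed <- remove_precursor_peaks(sp, 300, tol = 0.005, mode = "window")
  expect_equal(windowed$mz, c(100, 295, 305))
})

test_that("identical spectra score 1 and disjoint spectra score 0", {
  sp <- list(mz = c(100, 200, 300), intensity = c(10, 40, 20))
  self <- weighted_cosine(sp, sp)
  expect_equal(self$score, 1)
  expect_equal(self$matched_signals, 3L)
  far <- weighted_cosine(sp, list(mz = c(150, 250), intensity = c(5, 5)))
  expect_equal(far$score, 0)
  expect_equal(far$matched_signals, 0L)
})

test_that("the square-root weighting reproduces the hand-computed score", {
  a <- list(mz = c(100, 200), intensity = c(4, 9))
  b <- list(mz = c(100, 200), intensity = c(9, 4))
  got <- weighted_cosine(a, b)
  # w products: sqrt(4)sqrt(9) + sqrt(9)sqrt(4) = 12; norms 4+9 = 13 each
  expect_equal(got$score, 144 / 169)
  expect_equal(got$matched_signals, 2L)
  expect_equal(brute_force_cosine(a, b), 144 / 169)
})

test_that("the score is symmetric and intensity-scale invariant", {
  set.seed(61)
  for (i in 1:50) {
    a <- random_spectrum(); b <- random_spectrum()
    ab <- weighted_cosine(a, b, mz_tol = 5)
    ba <- weighted_cosine(b, a, mz_tol = 5)
    expect_equal(ab$score, ba$score, tolerance = 1e-12)
    b_scaled <- list(mz = b$mz, intensity = b$intensity * 123.4)
    expect_equal(weighted_cosine(a, b_scaled, mz_tol = 5)$score, ab$score,
                 tolerance = 1e-12)
    expect_gte(ab$score, 0); expect_lte(ab$score, 1)
    expect_lte(ab$matched_signals, min(length(a$mz), length(b$mz)))
  }
})

test_that("greedy pairing never beats the optimal assignment", {
  set.seed(62)
  n_equal <- 0L; n <- 300L
  for (i in seq_len(n)) {
    p <- random_match_pair(mz_tol = 0.02)
    greedy <- weighted_cosine(p$a, p$b, mz_tol = 0.02)$score
    optimal <- brute_force_cosine(p$a, p$b, mz_tol = 0.02)
    expect_lte(greedy, optimal + 1e-9)
    if (abs(greedy - optimal) < 1e-9) n_equal <- n_equal + 1L
  }
  expect_gte(n_equal / n, 0.95)
  # adversarially dense spectra may defeat the greedy choice, but the
  # optimality bound must still hold
  for (i in 1:100) {
    a <- random_spectrum(sample(1:6, 1), mz_range = c(100, 103))
    b <- random_spectrum(sample(1:6, 1), mz_range = c(100, 103))
    expect_lte(weighted_cosine(a, b, mz_tol = 1)$score,
               brute_force_cosine(a, b, mz_tol = 1) + 1e-9)
  }
})

test_that("library search enforces precursor, score and match-count gates", {
  set.seed(63)
  lib <- lapply(1:10, random_entry)
  lib[[4]] <- library_entry(name = "q4", precursor_mz = 500,
                            mz = c(100, 150, 200, 250, 300, 350),
                            intensity = c(5, 10, 40, 20, 80, 15))
  q <- lib[[4]]
  hits <- library_search(list(q), lib, min_matched = 2L)
  expect_gte(nrow(hits), 1L)
  expect_equal(hits$score[1], 1)
  expect_equal(hits$library_id[1], "q4#4")
  # precursor 1 Th away: no candidates
  q2 <- q; q2$precursor_mz <- q$precursor_mz + 1
  expect_equal(nrow(library_search(list(q2), lib, min_matched = 2L)), 0L)
})

test_that("three matched signals are rejected by the min-matched gate", {
  mk <- function(name) library_entry(name = name, precursor_mz = 400,
                                     mz = c(100, 150, 200),
                                     intensity = c(10, 20, 30))
  hits <- library_search(list(mk("q")), list(mk("l")))
  expect_equal(nrow(hits), 0L)  # perfect score but only 3 matched signals
  hits2 <- library_search(list(mk("q")), list(mk("l")), min_matched = 3L)
  expect_equal(nrow(hits2), 1L)
  expect_equal(hits2$matched_signals, 3L)
})

test_that("overlap patterns count first InChIKey blocks UpSet-style", {
  X <- "AAAAAAAAAAAAAA-AAAAAAAAAA-N"
  Y <- "BBBBBBBBBBBBBB-BBBBBBBBBB-N"
  ov <- overlap_sets(list(A = X, B = X))
  expect_equal(ov$pattern_counts[["A&B"]], 1L)
  expect_equal(unname(ov$per_source_unique), c(0L, 0L))
  ov2 <- overlap_sets(list(A = c(X, Y), B = Y))
  expect_equal(ov2$pattern_counts[["A"]], 1L)
  expect_equal(ov2$pattern_counts[["A&B"]], 1L)
  # a stereoisomer pair split across sources counts as shared
  ster <- overlap_sets(list(A = "AAAAAAAAAAAAAA-AAAAAAAAAA-N",
                            B = "AAAAAAAAAAAAAA-ZZZZZZZZZZ-N"))
  expect_equal(ster$pattern_counts[["A&B"]], 1L)
  expect_equal(ster$union_size, 1L)
  expect_error(overlap_sets(list(A = "short-key")), "malformed")
})

test_that("overlap pattern counts sum to the union of first blocks", {
  set.seed(64)
  pool <- vapply(1:40, function(i) {
    paste(sample(LETTERS, 14, TRUE), collapse = "")
  }, character(1))
  sources <- lapply(1:4, function(i) sample(pool, 15))
  names(sources) <- paste0("S", 1:4)
  ov <- overlap_sets(sources)
  expect_equal(sum(ov$pattern_counts), ov$union_size)
  expect_equal(ov$union_size, length(unique(unlist(sources))))
})

test_that("tanimoto similarity matches an independent bitset computation", {
  expect_equal(tanimoto_similarity("c1ccccc1", "c1ccccc1"), 1)
  tol <- tanimoto_similarity("c1ccccc1", "Cc1ccccc1")
  expect_gt(tol, 0); expect_lt(tol, 1)
  fa <- msnforest:::structure_fingerprint("c1ccccc1")
  fb <- msnforest:::structure_fingerprint("Cc1ccccc1")
  expect_equal(tol, sum(fa & fb) / sum(fa | fb))
  # structures with no shared fingerprint bits
  disjoint <- tanimoto_similarity("CCCC", "[Na+].[Cl-]")
  expect_equal(disjoint, 0)
})
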