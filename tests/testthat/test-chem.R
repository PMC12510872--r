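# Structure curation, descriptors and metadata bookkeeping.

test_that("salt stripping and neutralization yield the neutral parent", {
  expect_equal(standardize_structure("CC(=O)[O-].[Na+]"), "CC(=O)O")
  # covalently drawn sodium salt needs the metal-disconnection rule
  expect_equal(standardize_structure("CC(=O)O[Na]"), "CC(=O)O")
  # hydrochloride: counter-ion is the smaller fragment
  expect_equal(standardize_structure("CCN.Cl"), "CCN")
  # InChI input is detected by prefix
  expect_equal(standardize_structure("InChI=1S/C2H4O2/c1-2(3)4/h1H3,(H,3,4)"),
               "CC(=O)O")
})

test_that("standardization is idempotent and keeps stereochemistry", {
  cases <- c("CC(=O)[O-].[Na+]", "C[C@H](N)C(=O)O.Cl", "c1ccccc1C(=O)O",
             "CCN(CC)CC", "OC[C@H]1OC(O)[C@H](O)[C@@H](O)[C@@H]1O",
             "CC(=O)O[Na]", "[NH4+].CC(=O)[O-]")
  once <- standardize_structures(cases)$cleaned
  twice <- standardize_structures(once)$cleaned
  expect_false(anyNA(once))
  expect_identical(twice, once)
  # stereocentre survives curation of the chiral hydrochloride: the key's
  # second block must not be the no-stereo hash
  key <- compute_descriptors(once[2])$inchikey
  expect_match(key, "^[A-Z]{14}-[A-Z]{10}-[A-Z]$")
  expect_false(substr(key, 16, 25) == "UHFFFAOYSA")
})

test_that("uncurat(e)able records are rejected with reason codes", {
  res <- standardize_structures(c("", "not_a_smiles((", "CCO", NA))
  expect_equal(res$reason, c("empty_structure", "unparseable", NA,
                             "empty_structure"))
  expect_equal(res$cleaned[3], "CCO")
  expect_true(all(is.na(res$cleaned[c(1, 2, 4)])))
})

test_that("descriptors match hand-computed monoisotopic masses", {
  d <- compute_descriptors(c("OCC1OC(O)C(O)C(O)C1O", "O"))
  expect_equal(d$monoisotopic_mass[1], 180.0634, tolerance = 1e-3 / 180)
  expect_equal(d$monoisotopic_mass[2], 18.0106, tolerance = 1e-3 / 18)
  expect_equal(d$formula, c("C6H12O6", "H2O"))
  expect_true(all(grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", d$inchikey)))
  expect_true(all(abs(d$monoisotopic_mass -
                        vapply(d$formula, formula_monoisotopic_mass,
                               numeric(1))) < 1e-4))
})

test_that("stereoisomers share the connectivity block but not the full key", {
  d <- compute_descriptors(c("C[C@H](O)CC", "C[C@@H](O)CC"))
  expect_equal(substr(d$inchikey[1], 1, 14), substr(d$inchikey[2], 1, 14))
  expect_false(substr(d$inchikey[1], 16, 25) == substr(d$inchikey[2], 16, 25))
  expect_false(is.na(d$isomeric_smiles[1]))
})

test_that("formula masses agree with the OpenBabel exact-mass oracle", {
  set.seed(11)
  atoms <- c("C", "N", "O", "S")
  smiles <- vapply(1:50, function(i) {
    body <- paste(sample(atoms, sample(3:10, 1), replace = TRUE),
                  collapse = "")
    paste0("C", body, sample(c("", "Cl", "Br", "F"), 1))
  }, character(1))
  props <- msnforest:::ob_props(smiles)
  for (k in seq_along(smiles)) {
    mol <- ChemmineOB::forEachMol("SMILES", smiles[k], identity)
    oracle <- as.numeric(ChemmineOB::exactMass_OB(mol))
    expect_equal(formula_monoisotopic_mass(props$formula[k]), oracle,
                 tolerance = 1e-4 / oracle, label = smiles[k])
  }
})

test_that("formula parser handles multi-letter elements, groups and charge", {
  p <- parse_formula("C6H12O6")
  expect_equal(as.integer(p$counts[c("C", "H", "O")]), c(6L, 12L, 6L))
  expect_equal(parse_formula("C2H3O2-")$charge, -1L)
  expect_equal(parse_formula("Fe+2")$charge, 2L)
  expect_equal(parse_formula("Ca++")$charge, 2L)
  expect_equal(parse_formula("Ca(OH)2")$counts[["O"]], 2L)
  expect_equal(formula_monoisotopic_mass("CH3Cl"),
               12 + 3 * 1.00782503207 + 34.96885268, tolerance = 1e-9)
  expect_error(parse_formula("C6H(2"), "unbalanced")
  expect_error(formula_monoisotopic_mass("C6Hx2"), "no monoisotopic mass")
})

test_that("curate_compounds separates curated rows from rejects", {
  meta <- data.frame(
    name = c("acetate salt", "broken", "ethanol"),
    smiles = c("CC(=O)[O-].[Na+]", "xx((", "CCO"),
    library_code = "LIBX", plate = "1", well = c("A1", "A1", "A2"),
    stringsAsFactors = FALSE)
  res <- curate_compounds(meta)
  expect_equal(nrow(res$curated), 2L)
  expect_equal(res$rejects$reason, "unparseable")
  expect_equal(res$rejects$source_name, "broken")
  expect_equal(res$curated$unique_sample_id, c("LIBX_1_A1", "LIBX_1_A2"))
  expect_true(all(res$curated$monoisotopic_mass > 0))
  # curated structures carry no disconnected fragments
  expect_false(any(grepl(".", res$curated$cleaned_smiles, fixed = TRUE)))
})

test_that("sample identifiers are shared per well and distinct across wells", {
  df <- data.frame(library_code = "MCEBIO", plate = "1",
                   well = rep("A3", 10), stringsAsFactors = FALSE)
  out <- assign_sample_ids(df)
  expect_equal(unique(out$unique_sample_id), "MCEBIO_1_A3")
  two <- assign_sample_ids(data.frame(library_code = "MCEBIO",
                                      plate = c("1", "2"), well = "A3"))
  expect_equal(anyDuplicated(two$unique_sample_id), 0L)
  expect_error(assign_sample_ids(data.frame(library_code = "X", plate = "1",
                                            well = c("A1", NA))),
               "missing library/plate/well")
})

test_that("duplicate analysis distinguishes stereo and connectivity grouping", {
  keys <- c("AAAAAAAAAAAAAA-AAAAAAAAAA-N", "AAAAAAAAAAAAAA-BBBBBBBBBB-N",
            "CCCCCCCCCCCCCC-CCCCCCCCCC-N")
  with_stereo <- dedupe_structures(keys, stereo = TRUE)
  no_stereo <- dedupe_structures(keys, stereo = FALSE)
  expect_equal(with_stereo$unique_count, 3L)
  expect_equal(no_stereo$unique_count, 2L)
  expect_equal(with_stereo$total_count, 3L)
  expect_lte(no_stereo$unique_count, with_stereo$unique_count)
  expect_lte(with_stereo$unique_count, with_stereo$total_count)
  expect_error(dedupe_structures(c("bad-key")), "malformed")
})

test_that("acquisition sequences run positive then negative per plate", {
  wells <- data.frame(library_code = "LIBX", plate = "1", well = c("A1", "A2"),
                      stringsAsFactors = FALSE)
  seqd <- generate_sequence(wells, "2026-02-01", "FIMSN")
  expect_equal(nrow(seqd), 4L)
  expect_equal(seqd$polarity, c("positive", "positive", "negative", "negative"))
  expect_equal(seqd$injection_index, 1:4)
  expect_true(all(mapply(grepl, seqd$unique_sample_id, seqd$filename,
                         MoreArgs = list(fixed = TRUE))))
  expect_error(
    generate_sequence(data.frame(library_code = "L", plate = "1",
                                 well = c("A1", "a1")),
                      "2026-02-01", "M"),
    "duplicate well")
})

test_that("sequence row count is twice the well count across libraries", {
  set.seed(3)
  libs <- sprintf("LIB%d", 1:7)
  wells <- do.call(rbind, lapply(libs, function(l) {
    data.frame(library_code = l, plate = as.character(sample(1:3, 1)),
               well = sprintf("A%d", 1:sample(3:6, 1)),
               stringsAsFactors = FALSE)
  }))
  seqd <- generate_sequence(wells, "2026-02-01", "FIMSN")
  expect_equal(nrow(seqd), 2L * nrow(wells))
  # every filename resolves back to exactly one well
  meta <- assign_sample_ids(wells)
  for (i in seq_len(nrow(seqd))) {
    hit <- compounds_for_file(seqd$filename[i], meta)
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$unique_sample_id, seqd$unique_sample_id[i])
  }
})
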