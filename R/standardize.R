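#' Standardize a chemical structure to its neutral parent
#'
#' Cleans raw SMILES or InChI input to a single-component neutral parent
#' structure: an initial salt/solvate strip (keeping the largest fragment),
#' charge neutralization, then a second strip + neutralization pass. The
#' second pass catches salts that only become separable after the first
#' normalization (e.g. covalently drawn metal salts).
#'
#' Fragment selection keeps the fragment with the most heavy atoms; ties are
#' broken by larger monoisotopic mass, then by lexicographically smaller
#' canonical SMILES, so output is deterministic.
#'
#' @param raw a SMILES string, or an InChI string (detected by the
#'   `"InChI="` prefix).
#' @return canonical SMILES of the neutral parent, or `NA` with a `"reason"`
#'   attribute (`"empty_structure"` / `"unparseable"`) when the input cannot
#'   be curated.
#' @export
standardize_structure <- function(raw) {
  res <- standardize_structures(raw)
  out <- res$cleaned[1L]
  if (is.na(out)) attr(out, "reason") <- res$reason[1L]
  out
}

#' @rdname standardize_structure
#' @param raws character vector of raw structures.
#' @return `standardize_structures()`: list with `cleaned` (canonical SMILES
#'   or `NA`) and `reason` (`NA` or a reject reason code), both aligned with
#'   `raws`.
#' @export
standardize_structures <- function(raws) {
  n <- length(raws)
  cleaned <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)

  raws <- as.character(raws)
  empty <- is.na(raws) | !nzchar(trimws(raws))
  reason[empty] <- "empty_structure"
  todo <- which(!empty)
  if (!length(todo)) return(list(cleaned = cleaned, reason = reason))

  smi <- trimws(raws[todo])
  is_inchi <- startsWith(smi, "InChI=")
  if (any(is_inchi)) {
    smi[is_inchi] <- ob_convert(smi[is_inchi], from = "inchi", to = "can")
  }
  cur <- ob_convert(smi, from = "smi", to = "can")

  for (pass in 1:2) {
    ok <- which(!is.na(cur))
    if (!length(ok)) break
    cur[ok] <- vapply(cur[ok], disconnect_metals, character(1L))
    cur[ok] <- vapply(cur[ok], strip_to_largest_fragment, character(1L))
    cur[ok] <- ob_convert(cur[ok], from = "smi", to = "can",
                          ops = "--neutralize")
  }

  failed <- is.na(cur)
  reason[todo[failed]] <- "unparseable"
  cleaned[todo[!failed]] <- trimws(cur[!failed])
  list(cleaned = cleaned, reason = reason)
}

# Disconnect covalently drawn alkali-metal salts (M = Li/Na/K bonded to a
# neutral O or S) into the ionic form, so the usual strip + neutralize pass
# can remove the counter-ion. Operates on OpenBabel canonical SMILES, where
# these terminal metal atoms are written directly adjacent to their bonded
# atom. This is the pinned subset of metal-disconnection rules; salts drawn
# with an explicit "." disconnect never need it.
disconnect_metals <- function(can_smiles) {
  s <- can_smiles
  s <- gsub("([OS])\\[(Li|Na|K)\\]", "[\\1-].[\\2+]", s)
  s <- gsub("\\[(Li|Na|K)\\]([OS])", "[\\1+].[\\2-]", s)
  s
}

# Keep the largest connected component of a canonical SMILES. Components in
# OpenBabel canonical output are dot-separated at the top level, so a plain
# split is structurally safe.
strip_to_largest_fragment <- function(can_smiles) {
  frags <- strsplit(trimws(can_smiles), ".", fixed = TRUE)[[1L]]
  frags <- frags[nzchar(frags)]
  if (length(frags) <= 1L) return(trimws(can_smiles))
  props <- ob_props(frags)
  heavy <- vapply(props$formula, function(f) {
    if (is.na(f)) return(-1L)
    tryCatch(as.integer(heavy_atom_count(f)), error = function(e) -1L)
  }, integer(1L))
  mono <- vapply(props$formula, function(f) {
    if (is.na(f)) return(-1)
    tryCatch(formula_monoisotopic_mass(f), error = function(e) -1)
  }, numeric(1L))
  ord <- order(-heavy, -mono, frags)
  frags[ord[1L]]
}

#' Compute structure descriptors for curated compounds
#'
#' Derives, for each cleaned structure: canonical SMILES, isomeric SMILES
#' (absent when the structure carries no stereo information), InChI,
#' InChIKey, molecular formula, monoisotopic mass (summed from
#' most-abundant-isotope atomic masses of the formula) and an
#' atom-contribution logP estimate. logP is metadata only and is never used
#' in annotation or matching.
#'
#' @param cleaned character vector of curated single-component SMILES.
#' @return data.frame with columns `cleaned_smiles`, `isomeric_smiles`,
#'   `inchi`, `inchikey`, `formula`, `monoisotopic_mass`, `logp`; rows where
#'   descriptor computation failed have `NA` descriptors.
#' @export
compute_descriptors <- function(cleaned) {
  props <- ob_props(cleaned)
  inchi <- ob_convert(cleaned, from = "smi", to = "inchi")
  inchikey <- ob_convert(cleaned, from = "smi", to = "inchikey")
  mono <- vapply(props$formula, function(f) {
    if (is.na(f)) return(NA_real_)
    tryCatch(formula_monoisotopic_mass(f), error = function(e) NA_real_)
  }, numeric(1L), USE.NAMES = FALSE)
  has_stereo <- !is.na(props$cansmi) & !is.na(props$cansmiNS) &
    props$cansmi != props$cansmiNS
  data.frame(
    cleaned_smiles = props$cansmi,
    isomeric_smiles = ifelse(has_stereo, props$cansmi, NA_character_),
    inchi = inchi,
    inchikey = inchikey,
    formula = props$formula,
    monoisotopic_mass = mono,
    logp = props$logp,
    stringsAsFactors = FALSE
  )
}

is_valid_inchikey <- function(x) {
  !is.na(x) & grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", x)
}

#' Curate a compound metadata table
#'
#' Full metadata clean-up: structure standardization (salt stripping +
#' neutralization, two passes), descriptor computation and unique
#' sample-identifier assignment. Records whose structure cannot be parsed or
#' whose descriptors cannot be computed are diverted to a rejects table with
#' a reason code; they are reported, never silently dropped.
#'
#' @param metadata data.frame with one row per compound.
#' @param structure_col name of the column holding SMILES or InChI
#'   (auto-detected per value by the `"InChI="` prefix).
#' @param name_col,library_col,plate_col,well_col column names for the
#'   compound name and the library/plate/well triple.
#' @param enrich optional enrichment hook: a function taking and returning
#'   the curated data.frame (e.g. to append external database annotations).
#'   The package ships none and performs no network access; the hook is an
#'   extension point only.
#' @return list with `curated` (input columns plus all descriptor columns
#'   and `unique_sample_id`) and `rejects` (`row`, `source_name`,
#'   `raw_structure`, `reason`).
#' @export
curate_compounds <- function(metadata,
                             structure_col = "smiles",
                             name_col = "name",
                             library_col = "library_code",
                             plate_col = "plate",
                             well_col = "well",
                             enrich = NULL) {
  stopifnot(is.data.frame(metadata))
  for (col in c(structure_col, library_col, plate_col, well_col)) {
    if (!col %in% names(metadata)) stop("metadata lacks column '", col, "'")
  }
  raw <- as.character(metadata[[structure_col]])
  std <- standardize_structures(raw)
  desc <- compute_descriptors(std$cleaned)

  reason <- std$reason
  bad_desc <- is.na(reason) &
    (is.na(desc$monoisotopic_mass) | !is_valid_inchikey(desc$inchikey))
  reason[bad_desc] <- "descriptor_failure"

  keep <- is.na(reason)
  nm <- if (name_col %in% names(metadata)) as.character(metadata[[name_col]])
        else rep(NA_character_, nrow(metadata))
  rejects <- data.frame(
    row = which(!keep),
    source_name = nm[!keep],
    raw_structure = raw[!keep],
    reason = reason[!keep],
    stringsAsFactors = FALSE
  )

  curated <- metadata[keep, , drop = FALSE]
  curated$source_name <- nm[keep]
  curated$raw_structure <- raw[keep]
  curated <- cbind(curated, desc[keep, , drop = FALSE])
  names(curated)[names(curated) == library_col] <- "library_code"
  names(curated)[names(curated) == plate_col] <- "plate"
  names(curated)[names(curated) == well_col] <- "well"
  curated <- assign_sample_ids(curated)
  rownames(curated) <- NULL
  if (!is.null(enrich)) {
    stopifnot(is.function(enrich))
    curated <- enrich(curated)
  }
  list(curated = curated, rejects = rejects)
}
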