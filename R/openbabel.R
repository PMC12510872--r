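#' @importFrom ChemmineOB forEachMol prop_OB fingerprint_OB
NULL

# Low-level bridge to the OpenBabel `obabel` command-line converter.
#
# ChemmineOB's in-process convertFormat() discards stereochemistry during
# SMILES parsing, which corrupts InChIKey stereo layers, so all structure
# format conversions go through the obabel executable instead. Records are
# batched into a single obabel invocation with synthetic row titles; obabel
# aborts a batch at the first unparseable record, so rows missing from the
# output are retried one-by-one before being reported as failures (NA).

ob_binary <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p)) stop("the 'obabel' executable is required but was not found on PATH")
  p
}

ob_run <- function(args, input_lines) {
  out <- suppressWarnings(system2(ob_binary(), args,
                                  stdout = TRUE, stderr = FALSE,
                                  input = input_lines))
  out[nzchar(out)]
}

# Parse one obabel output line into c(value, title). Output layout depends on
# the target format: SMILES-like formats are "value\ttitle", inchi/inchikey
# with the -xt option are "value title".
ob_split_line <- function(line, to) {
  if (to %in% c("can", "smi")) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
  } else {
    parts <- strsplit(sub(" ", "\x01", line, fixed = TRUE), "\x01", fixed = TRUE)[[1]]
  }
  if (length(parts) < 2L) c(parts[1L], NA_character_) else c(parts[1L], trimws(parts[2L]))
}

ob_format_args <- function(from, to, ops) {
  args <- c(paste0("-i", from), paste0("-o", to))
  if (to %in% c("inchi", "inchikey")) args <- c(args, "-xt")
  c(args, ops)
}

#' Convert structure strings with OpenBabel
#'
#' Vectorized conversion between structure formats (canonical SMILES, InChI,
#' InChIKey) with optional OpenBabel transformation ops such as
#' `--neutralize`. Unconvertible inputs yield `NA` rather than an error.
#'
#' @param x character vector of structures in format `from`.
#' @param from input format (`"smi"` or `"inchi"`).
#' @param to output format (`"can"`, `"smi"`, `"inchi"`, `"inchikey"`).
#' @param ops extra obabel arguments, e.g. `"--neutralize"`.
#' @return character vector aligned with `x`; `NA` where conversion failed.
#' @keywords internal
ob_convert <- function(x, from = "smi", to = "can", ops = character()) {
  n <- length(x)
  res <- rep(NA_character_, n)
  ok <- !is.na(x) & nzchar(trimws(x))
  if (!any(ok)) return(res)
  idx <- which(ok)
  if (from == "inchi") {
    # the InChI reader does not tolerate inline titles: convert one by one
    for (i in idx) {
      out1 <- ob_run(c("-iinchi", paste0("-o", to), ops), trimws(x[i]))
      if (length(out1) >= 1L) res[i] <- ob_split_line(out1[1L], to)[1L]
    }
    return(res)
  }
  titles <- paste0("r", idx)
  lines <- paste(trimws(x[idx]), titles)
  out <- ob_run(ob_format_args(from, to, ops), lines)
  got <- vapply(out, ob_split_line, character(2L), to = to)
  if (length(got)) {
    hit <- match(got[2L, ], titles)
    keep <- !is.na(hit)
    res[idx[hit[keep]]] <- got[1L, keep]
  }
  # obabel stops a batch at the first bad record: retry the unresolved rows
  # individually so one malformed structure cannot shadow the rest.
  missing <- idx[is.na(res[idx])]
  if (length(missing) && length(idx) > 1L) {
    for (i in missing) {
      out1 <- ob_run(ob_format_args(from, to, ops), paste(trimws(x[i]), "r1"))
      if (length(out1) == 1L) res[i] <- ob_split_line(out1, to)[1L]
    }
  }
  res
}

# In-process OpenBabel properties (safe fields only: prop_OB's InChI output
# is unreliable, so InChI goes through ob_convert instead).
ob_props_one <- function(smiles) {
  res <- tryCatch(
    forEachMol("SMILES", smiles, function(m) {
      p <- prop_OB(m)
      c(cansmi = p$cansmi, cansmiNS = p$cansmiNS, formula = p$formula,
        logp = as.character(p$logP))
    }),
    error = function(e) NULL)
  if (is.null(res) || !length(res)) {
    return(c(cansmi = NA_character_, cansmiNS = NA_character_,
             formula = NA_character_, logp = NA_character_))
  }
  res[[1L]]
}

#' @keywords internal
ob_props <- function(smiles) {
  rows <- lapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) {
      c(cansmi = NA_character_, cansmiNS = NA_character_,
        formula = NA_character_, logp = NA_character_)
    } else ob_props_one(s)
  })
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  out$logp <- suppressWarnings(as.numeric(out$logp))
  out
}

# Circular (extended-connectivity, radius 2) fingerprint folded to 2048 bits.
ob_morgan_fp <- function(smiles, nbits = 2048L) {
  fp <- tryCatch({
    mol <- forEachMol("SMILES", smiles, identity)
    fingerprint_OB(mol, "ECFP4")
  }, error = function(e) NULL)
  if (is.null(fp) || !length(fp)) stop("cannot parse structure: ", smiles)
  bits <- as.numeric(unlist(fp, use.names = FALSE)) > 0
  if (length(bits) %% nbits != 0L) stop("fingerprint length not a multiple of nbits")
  apply(matrix(bits, nrow = nbits), 1L, any)
}
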