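# Monoisotopic (most-abundant-isotope) atomic masses, CODATA/AME-derived
# values as tabulated for exact-mass work in small-molecule MS.
MONOISOTOPIC_MASS <- c(
  H  = 1.00782503207,  D  = 2.01410177785, C  = 12.0,
  N  = 14.0030740048,  O  = 15.9949146196, F  = 18.99840322,
  Na = 22.9897692809,  Mg = 23.985041700,  Si = 27.9769265325,
  P  = 30.97376163,    S  = 31.97207100,   Cl = 34.96885268,
  K  = 38.96370668,    Ca = 39.96259098,   Mn = 54.9380451,
  Fe = 55.9349375,     Co = 58.9331950,    Ni = 57.9353429,
  Cu = 62.9295975,     Zn = 63.9291422,    As = 74.9215965,
  Se = 79.9165213,     Br = 78.9183371,    I  = 126.904473,
  B  = 11.0093054,     Li = 7.01600455,    Al = 26.98153863,
  Sn = 119.9021947,    Ag = 106.905097,    Au = 196.9665687,
  Pt = 194.9647911,    Hg = 201.970643,    W  = 183.9509312,
  Ti = 47.9479463,     Cr = 51.9405075,    V  = 50.9439595,
  Mo = 97.9054082,     Ba = 137.9052472,   Sr = 87.9056121,
  Rb = 84.911789738,   Cs = 132.905451933, Bi = 208.9803987,
  Sb = 120.9038157,    Te = 129.9062244,   Ge = 73.9211778,
  Ga = 68.9255736,     Gd = 157.9241039,   Pd = 105.903486,
  Ru = 101.9043493,    Zr = 89.9047044,    Nb = 92.9063781
)

PROTON_MASS   <- 1.007276466879  # H minus one electron, Da
ELECTRON_MASS <- 0.000548579909  # Da

#' Parse a flat molecular formula
#'
#' Accepts Hill-notation formulas as emitted by OpenBabel (e.g. `"C6H12O6"`,
#' `"C2H3O2-"`); a trailing charge suffix (`+`, `-`, `+2`, `2-`, ...) is
#' parsed and returned separately. Parenthesized groups are expanded.
#'
#' @param formula a single formula string.
#' @return list with `counts` (named integer vector of element counts) and
#'   `charge` (integer).
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, !is.na(formula))
  f <- gsub("[[:space:]]", "", formula)
  charge <- 0L
  # charge suffix: a run of +/- signs ("Ca++") or sign-then-digits ("Fe+2");
  # a digit before the sign belongs to an element count ("C2H3O2-" is -1)
  chg <- regmatches(f, regexpr("([+-]+|[+-][0-9]+)$", f))
  if (length(chg) && nzchar(chg)) {
    sign <- if (grepl("-", chg, fixed = TRUE)) -1L else 1L
    digits <- gsub("[+-]", "", chg)
    charge <- sign * (if (nzchar(digits)) as.integer(digits)
                      else nchar(gsub("[^+-]", "", chg)))
    f <- substr(f, 1L, nchar(f) - nchar(chg))
  }
  counts <- parse_formula_group(f)
  if (length(counts)) {
    counts <- tapply(counts, names(counts), sum)
    counts <- counts[order(names(counts))]
  }
  list(counts = counts, charge = charge)
}

# Recursive descent over one formula segment (handles nested parentheses).
parse_formula_group <- function(f) {
  counts <- integer(0)
  i <- 1L
  n <- nchar(f)
  while (i <= n) {
    ch <- substr(f, i, i)
    if (ch == "(") {
      depth <- 1L; j <- i
      while (depth > 0L) {
        j <- j + 1L
        if (j > n) stop("unbalanced parenthesis in formula: ", f)
        cj <- substr(f, j, j)
        if (cj == "(") depth <- depth + 1L
        if (cj == ")") depth <- depth - 1L
      }
      inner <- parse_formula_group(substr(f, i + 1L, j - 1L))
      i <- j + 1L
      mult <- 1L
      m <- regmatches(substr(f, i, n), regexpr("^[0-9]+", substr(f, i, n)))
      if (length(m) && nzchar(m)) { mult <- as.integer(m); i <- i + nchar(m) }
      counts <- c(counts, inner * mult)
    } else {
      rest <- substr(f, i, n)
      m <- regmatches(rest, regexpr("^[A-Z][a-z]?", rest))
      if (!length(m) || !nzchar(m)) stop("cannot parse formula at '", rest, "'")
      i <- i + nchar(m)
      rest <- substr(f, i, n)
      cnt <- regmatches(rest, regexpr("^[0-9]+", rest))
      k <- 1L
      if (length(cnt) && nzchar(cnt)) { k <- as.integer(cnt); i <- i + nchar(cnt) }
      counts <- c(counts, stats::setNames(k, m))
    }
  }
  counts
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of most-abundant-isotope atomic masses over the formula's element
#' counts, with an electron-mass correction for charged formulas.
#'
#' @param formula formula string (see [parse_formula()]).
#' @return monoisotopic mass in Da.
#' @examples
#' formula_monoisotopic_mass("C6H12O6")  # 180.0634
#' @export
formula_monoisotopic_mass <- function(formula) {
  p <- parse_formula(formula)
  unknown <- setdiff(names(p$counts), names(MONOISOTOPIC_MASS))
  if (length(unknown)) {
    stop("no monoisotopic mass tabulated for element(s): ",
         paste(unknown, collapse = ", "))
  }
  sum(MONOISOTOPIC_MASS[names(p$counts)] * p$counts) - p$charge * ELECTRON_MASS
}

heavy_atom_count <- function(formula) {
  p <- parse_formula(formula)
  sum(p$counts[setdiff(names(p$counts), c("H", "D"))])
}
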