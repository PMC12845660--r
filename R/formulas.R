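## Elemental-formula arithmetic shared by every stage of the workflow.
## All masses in Da; monoisotopic = most abundant isotope.

# Monoisotopic atomic masses (CODATA/IUPAC), restricted to the element set
# supported by the screening schema.
.ATOMIC_MASS <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  F  = 18.99840322,
  P  = 30.97376163,
  S  = 31.97207100,
  Cl = 34.96885268,
  Br = 78.9183371
)

.ELECTRON_MASS <- 0.000548579909
.PROTON_MASS   <- 1.007276466879
# spacing used to place aggregated isotopologue peaks (13C-12C difference)
.ISOTOPE_SPACING <- 1.0033548

#' Supported chemical elements
#'
#' The element set admitted by formula parsing, enumeration and mass
#' computation: C, H, N, O, F, P, S, Cl, Br. N is included so that
#' fluorinated pesticides on suspect lists can be represented alongside
#' classical CHFO/S PFAS.
#'
#' @return Character vector of element symbols.
#' @export
supportedElements <- function() names(.ATOMIC_MASS)

#' Parse a molecular formula string
#'
#' Converts a Hill-style formula such as `"C8HF15O2"` into a named integer
#' vector of element counts. Only the elements in [supportedElements()] are
#' admitted.
#'
#' @param formula Character scalar, e.g. `"C2HF3O2"` (TFA). A named numeric
#'   vector of counts is passed through after validation.
#' @return Named integer vector of element counts.
#' @examples
#' parseFormula("C2HF3O2")
#' @export
parseFormula <- function(formula) {
  if (is.numeric(formula) && !is.null(names(formula))) {
    counts <- formula
  } else {
    if (!is.character(formula) || length(formula) != 1L || is.na(formula) ||
        !nzchar(formula)) {
      stop("formula must be a nonempty character scalar or named count vector")
    }
    s <- gsub("[[:space:]]", "", formula)
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
    tokens <- regmatches(s, gregexpr("([A-Z][a-z]?)([0-9]*)", s))[[1]]
    if (sum(attr(m, "match.length")) != nchar(s) || length(tokens) == 0L) {
      stop("cannot parse formula: '", formula, "'")
    }
    el <- sub("[0-9]*$", "", tokens)
    n <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                           sub("^[A-Za-z]+", "", tokens), "1"))
    counts <- tapply(n, el, sum)
  }
  bad <- setdiff(names(counts), supportedElements())
  if (length(bad)) {
    stop("unknown element(s) in formula: ", paste(bad, collapse = ", "))
  }
  if (any(counts != round(counts)) || any(counts < 0)) {
    stop("element counts must be positive integers")
  }
  counts <- counts[counts > 0]
  if (length(counts) == 0L) stop("formula is empty")
  out <- as.integer(counts)
  names(out) <- names(counts)
  # canonical Hill order: C, H, then alphabetical
  ord <- order(match(names(out), c("C", "H"), nomatch = 3L), names(out))
  out[ord]
}

#' Format element counts as a formula string
#'
#' @param counts Named integer vector as returned by [parseFormula()].
#' @return Character scalar in Hill order.
#' @export
formatFormula <- function(counts) {
  counts <- parseFormula(counts)
  paste0(names(counts), ifelse(counts > 1L, counts, ""), collapse = "")
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of most-abundant-isotope atomic masses over the formula.
#'
#' @param formula Formula string or named count vector.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' monoisotopicMass("C2HF3O2") # TFA, 113.99286 Da
#' monoisotopicMass("CF2")     # repeat unit, 49.9968066 Da
#' @export
monoisotopicMass <- function(formula) {
  counts <- parseFormula(formula)
  sum(.ATOMIC_MASS[names(counts)] * counts)
}

#' m/z of the deprotonated ion
#'
#' The workflow observes PFAS as singly charged `[M-H]-` ions in negative
#' electrospray; the ion m/z is the neutral monoisotopic mass minus the mass
#' of a proton (equivalently, minus H plus an electron).
#'
#' @param neutralMass Neutral monoisotopic mass in Da (or a formula, which is
#'   converted first).
#' @return m/z of `[M-H]-` in Da.
#' @examples
#' deprotonatedMz("C8HF15O2") # PFOA [M-H]-, 412.96643
#' @export
deprotonatedMz <- function(neutralMass) {
  if (is.character(neutralMass) ||
      (!is.null(names(neutralMass)) && is.numeric(neutralMass))) {
    neutralMass <- monoisotopicMass(neutralMass)
  }
  stopifnot(is.numeric(neutralMass), all(neutralMass > 0))
  neutralMass - .PROTON_MASS
}

#' m/z of a fragment anion
#'
#' Mass of a fragment given as an intact anion formula (all atoms already
#' present), i.e. formula mass plus one electron.
#'
#' @param formula Fragment formula, e.g. `"CF3"` for the trifluoromethyl
#'   anion.
#' @return m/z in Da.
#' @export
fragmentAnionMz <- function(formula) {
  monoisotopicMass(formula) + .ELECTRON_MASS
}

# parts-per-million mass error of measured vs theoretical
ppmError <- function(measured, theoretical) {
  (measured - theoretical) / theoretical * 1e6
}
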