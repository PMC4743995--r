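# Monoisotopic mass arithmetic.
#
# All masses are fixed to a bundled constant table (IUPAC/CODATA monoisotopic
# values, >= 6 decimals) so that mass computations are bit-reproducible across
# environments and never depend on an external chemistry library.

#' Monoisotopic atomic masses (Da)
#'
#' Named vector of monoisotopic atomic masses of the elements recognized by
#' [parse_formula()]. Values are IUPAC/CODATA monoisotopic masses of the most
#' abundant isotope, in dalton.
#'
#' @format Named numeric vector.
#' @export
atomic_masses <- c(
  H  = 1.00782503207,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.97376163,
  S  = 31.97207100,
  Na = 22.9897692809,
  K  = 38.96370668,
  Cl = 34.96885268,
  F  = 18.99840322,
  Br = 78.9183371,
  I  = 126.904473,
  Fe = 55.9349375,
  Mg = 23.9850417,
  Ca = 39.96259098,
  Mn = 54.9380451,
  Zn = 63.9291422,
  Cu = 62.9295975,
  Co = 58.9331950,
  Ni = 57.9353429,
  Mo = 97.9054082,
  Se = 79.9165213,
  B  = 11.0093054,
  Si = 27.9769265325
)

#' Physical mass constants (Da)
#'
#' `proton_mass` is the mass of a proton (so that the m/z of a deprotonated
#' ion is the neutral mass minus `proton_mass`, with the electron mass handled
#' correctly). `c13_delta` is the mass difference between 13C and 12C, i.e.
#' the offset of a one-carbon isotopologue.
#'
#' @name mass-constants
NULL

#' @rdname mass-constants
#' @export
proton_mass <- 1.007276467

#' @rdname mass-constants
#' @export
c13_delta <- 1.0033548378

#' Parse an elemental formula
#'
#' Parses a Hill-style elemental formula such as `"C5H9NO4"` into a named
#' count vector. Only the elements listed in [atomic_masses] are recognized;
#' anything else is an error (there is no silent fallback, since a wrong
#' element would corrupt every downstream m/z window query).
#'
#' @param formula Character scalar, e.g. `"C6H12O6"`.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C5H9NO4")
#' @export
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula) ||
      !nzchar(formula)) {
    stop("'formula' must be a single non-empty string")
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula)) {
    stop(sprintf("cannot parse formula '%s'", formula))
  }
  elems <- sub("[0-9]*$", "", tokens)
  counts <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                              sub("^[A-Za-z]+", "", tokens), "1"))
  unknown <- setdiff(elems, names(atomic_masses))
  if (length(unknown)) {
    stop(sprintf("unknown element(s) in formula '%s': %s",
                 formula, paste(unknown, collapse = ", ")))
  }
  agg <- tapply(counts, factor(elems, levels = unique(elems)), sum)
  out <- stats::setNames(as.integer(agg), names(agg))
  out[out > 0L]
}

#' Neutral monoisotopic mass of a formula
#'
#' @param formula Character vector of elemental formulas.
#' @return Numeric vector of neutral monoisotopic masses in Da.
#' @examples
#' monoisotopic_mass("H2O")       # 18.0105646...
#' monoisotopic_mass("C5H9NO4")   # glutamate, 147.0531577...
#' @export
monoisotopic_mass <- function(formula) {
  vapply(formula, function(f) {
    counts <- parse_formula(f)
    sum(atomic_masses[names(counts)] * counts)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Ion species recognized by the annotation stage
#'
#' Negative-mode flow-injection spectra are annotated as deprotonated
#' molecular ions and their one-carbon 13C isotopologues.
#'
#' @export
ion_species <- c("[M-H]-", "[M-H]+13C")

#' Expected m/z of an ion species
#'
#' Converts a neutral monoisotopic mass into the m/z expected in negative
#' ionization mode: `"[M-H]-"` subtracts one proton mass; `"[M-H]+13C"`
#' additionally adds the 13C-12C mass difference (one 12C replaced by 13C).
#'
#' @param mass Numeric vector of neutral monoisotopic masses (Da), all > 0.
#' @param species One of [ion_species].
#' @return Numeric vector of expected m/z values (Da).
#' @examples
#' expected_mz(147.0531577, "[M-H]-")     # 146.0458812
#' expected_mz(147.0531577, "[M-H]+13C")  # 147.0492361
#' @export
expected_mz <- function(mass, species = ion_species) {
  species <- match.arg(species)
  if (!is.numeric(mass) || any(!is.finite(mass)) || any(mass <= 0)) {
    stop("'mass' must be positive and finite")
  }
  mz <- mass - proton_mass
  if (species == "[M-H]+13C") mz <- mz + c13_delta
  mz
}
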