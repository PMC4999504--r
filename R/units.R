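# Package-wide unit system: Angstrom, ps, amu, K, kcal/mol, cm^-1; densities g/cc.

#' Physical constants used throughout the package
#'
#' A named list of the constants the analyses rely on, in the package unit
#' system (Angstrom, ps, amu, K, kcal/mol, cm\eqn{^{-1}}).
#'
#' @format Named list with elements:
#' \describe{
#'   \item{kB}{Boltzmann constant, kcal/mol/K.}
#'   \item{amu_g}{1 atomic mass unit in grams.}
#'   \item{c_cm_s}{Speed of light, cm/s.}
#'   \item{water_mass}{Molar mass of water, amu.}
#' }
#' @export
hf_constants <- list(
  kB = 0.0019872041,
  amu_g = 1.66053906660e-24,
  c_cm_s = 2.99792458e10,
  water_mass = 18.0154
)

# minimal element -> mass table (amu); beads get their own masses
.element_masses <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999,
  S = 32.06, P = 30.974, NA_ = 22.990, CL = 35.45, K = 39.098,
  B = 72.0 # generic coarse-grained bead
)

#' Look up atomic masses by element symbol
#'
#' @param element character vector of element symbols ("H", "C", "O", ...;
#'   "B" is reserved for generic coarse-grained beads, 72 amu).
#' @return numeric vector of masses in amu.
#' @export
element_mass <- function(element) {
  key <- toupper(element)
  key[key == "NA"] <- "NA_"
  m <- .element_masses[key]
  if (anyNA(m)) {
    stop("unknown element(s): ", paste(unique(element[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

#' Guess the element from an atom name
#'
#' PDB-style heuristics: strip digits, take the leading one or two letters,
#' preferring a two-letter match in the element table.
#'
#' @param name character vector of atom names.
#' @return character vector of element symbols.
#' @export
guess_element <- function(name) {
  vapply(name, function(nm) {
    s <- gsub("[^A-Za-z]", "", nm)
    if (nchar(s) == 0L) return("C")
    one <- toupper(substr(s, 1, 1))
    if (one %in% names(.element_masses)) one else "C"
  }, character(1), USE.NAMES = FALSE)
}
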