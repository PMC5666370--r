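#' Atomic mass constants
#'
#' Monoisotopic and average atomic masses used throughout the package, plus
#' the proton mass used for ESI charge-state arithmetic. Monoisotopic values
#' are the masses of the most abundant isotope of each element; peptide
#' masses reported by high-resolution LC-ESI-MS are monoisotopic.
#'
#' @param kind `"monoisotopic"` or `"average"`.
#' @return Named numeric vector of atomic masses in Da.
#' @examples
#' atomic_masses()[["O"]]
#' @export
atomic_masses <- function(kind = c("monoisotopic", "average")) {
  kind <- match.arg(kind)
  switch(kind,
    monoisotopic = c(
      C = 12.000000,
      H = 1.0078250319,
      N = 14.0030740052,
      O = 15.9949146221,
      S = 31.97207069
    ),
    average = c(
      C = 12.0107,
      H = 1.00794,
      N = 14.0067,
      O = 15.9994,
      S = 32.065
    )
  )
}

#' Mass of a proton in Da (ESI protonation convention)
#'
#' Used for charge projection and deconvolution of multiply protonated ions.
#' This is the proton mass, not the hydrogen-atom mass: electrospray adds
#' H+ (no electron).
#'
#' @export
PROTON_MASS <- 1.00727646

# identifier for the constants above; stamped into reports so numbers are
# auditable against a specific constant set
MASS_TABLE_VERSION <- "venompep-monoiso-1"

# residue (i.e. dehydrated amino acid) elemental compositions of the 20
# standard amino acids; Leu/Ile are distinct letters with identical formulas
.residue_formulas <- list(
  G = c(C = 2L,  H = 3L,  N = 1L, O = 1L),
  A = c(C = 3L,  H = 5L,  N = 1L, O = 1L),
  S = c(C = 3L,  H = 5L,  N = 1L, O = 2L),
  P = c(C = 5L,  H = 7L,  N = 1L, O = 1L),
  V = c(C = 5L,  H = 9L,  N = 1L, O = 1L),
  T = c(C = 4L,  H = 7L,  N = 1L, O = 2L),
  C = c(C = 3L,  H = 5L,  N = 1L, O = 1L, S = 1L),
  L = c(C = 6L,  H = 11L, N = 1L, O = 1L),
  I = c(C = 6L,  H = 11L, N = 1L, O = 1L),
  N = c(C = 4L,  H = 6L,  N = 2L, O = 2L),
  D = c(C = 4L,  H = 5L,  N = 1L, O = 3L),
  Q = c(C = 5L,  H = 8L,  N = 2L, O = 2L),
  K = c(C = 6L,  H = 12L, N = 2L, O = 1L),
  E = c(C = 5L,  H = 7L,  N = 1L, O = 3L),
  M = c(C = 5L,  H = 9L,  N = 1L, O = 1L, S = 1L),
  H = c(C = 6L,  H = 7L,  N = 3L, O = 1L),
  F = c(C = 9L,  H = 9L,  N = 1L, O = 1L),
  R = c(C = 6L,  H = 12L, N = 4L, O = 1L),
  Y = c(C = 9L,  H = 9L,  N = 1L, O = 2L),
  W = c(C = 11L, H = 10L, N = 2L, O = 1L)
)

#' Standard amino-acid residue table
#'
#' Residue (dehydrated) elemental formulas and monoisotopic masses for the
#' 20 standard amino acids. Nonstandard letters (B, Z, X, U, O) are
#' deliberately absent and rejected by the mass engine rather than
#' approximated. Leucine and isoleucine are distinct letters with identical
#' formulas and therefore identical masses.
#'
#' @return A tibble with columns `residue`, `formula` (Hill-order text) and
#'   `mass` (monoisotopic, Da).
#' @examples
#' amino_acid_table()
#' @export
amino_acid_table <- function() {
  masses <- atomic_masses("monoisotopic")
  tibble::tibble(
    residue = names(.residue_formulas),
    formula = vapply(
      .residue_formulas,
      function(f) format_formula(elemental_formula(f)),
      character(1), USE.NAMES = FALSE
    ),
    mass = vapply(
      .residue_formulas,
      function(f) sum(masses[names(f)] * f),
      numeric(1), USE.NAMES = FALSE
    )
  )
}
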