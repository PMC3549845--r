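## Monoisotopic mass conventions used throughout the package.

#' Physical mass constants (monoisotopic, Dalton)
#'
#' Proton, water, ammonia and carbon monoxide masses used for fragment-ion
#' m/z arithmetic. Exported as a named numeric vector so that tests and
#' downstream code share one set of conventions.
#'
#' @format Named numeric vector with elements `proton`, `water`, `ammonia`,
#'   `co`.
#' @export
MASS_CONST <- c(
  proton  = 1.007276466,
  water   = 18.010564684,
  ammonia = 17.026549101,
  co      = 27.994914620
)

#' Monoisotopic residue masses
#'
#' Masses (Da) of the 20 standard amino-acid residues (i.e. the mass each
#' residue adds to a peptide chain). Leucine and isoleucine are exactly
#' isobaric; glutamine and lysine differ by 0.03638 Da.
#'
#' @format Named numeric vector, names are one-letter residue codes.
#' @export
RESIDUE_MASS <- c(
  G =  57.02146374, A =  71.03711379, S =  87.03202841, P =  97.05276385,
  V =  99.06841391, T = 101.04767847, C = 103.00918448, L = 113.08406398,
  I = 113.08406398, N = 114.04292744, D = 115.02694302, Q = 128.05857750,
  K = 128.09496302, E = 129.04259309, M = 131.04048509, H = 137.05891186,
  F = 147.06841391, R = 156.10111102, Y = 163.06332853, W = 186.07931295
)

## the 20 standard residue letters (RESIDUE_MASS has 19 names; I == L mass)
AA20 <- local({
  v <- names(RESIDUE_MASS)
  v  # all 20 letters are present as names (I and L listed separately)
})
ALLOWED_AA <- c(AA20, "X")

#' Neutral monoisotopic mass of a peptide
#'
#' Sum of residue masses plus one water (the intact, uncharged peptide).
#'
#' @param sequence Character scalar of one-letter residue codes.
#' @return Neutral mass in Dalton.
#' @export
#' @examples
#' peptide_mass("PEPTIDE")
peptide_mass <- function(sequence) {
  residue_sum(sequence) + MASS_CONST[["water"]]
}

#' Sum of residue masses of a peptide (no terminal groups)
#'
#' @param sequence Character scalar of one-letter residue codes.
#' @return Residue-mass sum in Dalton.
#' @export
residue_sum <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  res <- strsplit(sequence, "")[[1]]
  bad <- setdiff(res, names(RESIDUE_MASS))
  if (length(bad) > 0L) {
    stop("unknown residue(s): ", paste(unique(bad), collapse = ", "))
  }
  sum(RESIDUE_MASS[res])
}

#' Precursor m/z of a peptide at a given charge
#'
#' @param sequence Peptide sequence.
#' @param charge Positive integer charge state.
#' @return m/z in Thomson.
#' @export
precursor_mz <- function(sequence, charge) {
  stopifnot(charge >= 1)
  (peptide_mass(sequence) + charge * MASS_CONST[["proton"]]) / charge
}

## Neutral (uncharged) precursor mass implied by precursor m/z and charge.
neutral_mass <- function(prec_mz, charge) {
  prec_mz * charge - charge * MASS_CONST[["proton"]]
}
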