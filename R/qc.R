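#' Number of consecutive sections obtainable from a tissue
#'
#' Planning helper: a tissue of length `tissue_length_mm` cut at
#' `thickness_um` per section yields
#' `floor(1000 * tissue_length_mm / thickness_um)` sections — e.g. a
#' 3.5 mm muscle at 20 um gives 175 consecutive sections.
#'
#' @param tissue_length_mm Tissue length in millimetres (> 0).
#' @param thickness_um Section thickness in micrometres (> 0).
#' @return Integer section count.
#' @export
section_count <- function(tissue_length_mm, thickness_um) {
  if (!is.numeric(tissue_length_mm) || tissue_length_mm <= 0 ||
      !is.numeric(thickness_um) || thickness_um <= 0) {
    stop("tissue length and section thickness must be positive",
         call. = FALSE)
  }
  as.integer(floor(1000 * tissue_length_mm / thickness_um))
}

#' Theoretical m/z of a peptide (iRT QC helper)
#'
#' Computes the monoisotopic m/z of an unmodified peptide at a given
#' charge, `(sum of residue masses + water + charge * proton) / charge`,
#' for checking spiked retention-time standard peptides in Skyline. Uses
#' the standard monoisotopic residue masses (water 18.010565, proton
#' 1.007276 Da); reported to 4 decimals.
#'
#' @param sequence Peptide sequence using the 20 standard one-letter
#'   residue codes.
#' @param charge Positive integer charge (default 2, the usual iRT
#'   precursor charge).
#' @return m/z in Daltons per unit charge, rounded to 4 decimals.
#' @export
#' @examples
#' irt_mz("LGGNEQVTR", 2) # 487.2567
irt_mz <- function(sequence, charge = 2L) {
  stopifnot(is.character(sequence), length(sequence) == 1,
            charge >= 1, charge == as.integer(charge))
  aa <- strsplit(toupper(sequence), "")[[1]]
  if (length(aa) == 0) stop("empty sequence", call. = FALSE)
  unknown <- which(!aa %in% names(MONOISOTOPIC_RESIDUE_MASS))
  if (length(unknown)) {
    stop("unknown residue '", aa[unknown[1]], "' at position ", unknown[1],
         call. = FALSE)
  }
  masses <- MONOISOTOPIC_RESIDUE_MASS[aa]
  mz <- (sum(masses) + MASS_WATER + charge * MASS_PROTON) / charge
  round(mz, 4)
}

# Monoisotopic residue (amino-acid minus water) masses, Da.
MONOISOTOPIC_RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931
)
MASS_WATER <- 18.010565
MASS_PROTON <- 1.007276
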