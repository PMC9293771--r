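# Monoisotopic constants (IUPAC atomic masses). Residue masses are the
# standard amino-acid residue (dehydrated) monoisotopic masses.

#' Physical constants for peptide mass computation
#'
#' Monoisotopic masses used throughout: `PROTON_MASS` (1.007276 Da),
#' `WATER_MASS` (18.010565 Da), `HYDROXYLATION_DELTA` (+15.994915 Da,
#' the single-oxygen mass shift that appears as the "~16 Da change" in
#' b/y series of hydroxylated peptides), and `THIOETHER_CYCLIZATION_DELTA`
#' (-35.976678 Da, loss of HCl on chloroacetyl/Cys thioether macrocycle
#' formation in synthetic cyclic assay peptides).
#'
#' @name mass-constants
#' @aliases PROTON_MASS WATER_MASS HYDROXYLATION_DELTA
#'   THIOETHER_CYCLIZATION_DELTA RESIDUE_MASSES
NULL

#' @rdname mass-constants
#' @export
PROTON_MASS <- 1.00727646688

#' @rdname mass-constants
#' @export
WATER_MASS <- 18.0105646863

#' @rdname mass-constants
#' @export
HYDROXYLATION_DELTA <- 15.9949146221

#' @rdname mass-constants
#' @export
THIOETHER_CYCLIZATION_DELTA <- -35.976678

#' @rdname mass-constants
#' @format `RESIDUE_MASSES`: named numeric vector over the 20 canonical
#'   residues (Da).
#' @export
RESIDUE_MASSES <- c(
  G = 57.02146374, A = 71.03711379, S = 87.03202841, P = 97.05276385,
  V = 99.06841391, T = 101.04767847, C = 103.00918448, L = 113.08406398,
  I = 113.08406398, N = 114.04292744, D = 115.02694302, Q = 128.05857751,
  K = 128.09496302, E = 129.04259309, M = 131.04048461, H = 137.05891186,
  F = 147.06841391, R = 156.10111102, Y = 163.06332853, W = 186.07931295
)

validate_modifications <- function(sequence, modifications) {
  if (is.null(modifications) || nrow(modifications) == 0L) {
    return(data.frame(position = integer(), mass_delta = numeric()))
  }
  stopifnot(all(c("position", "mass_delta") %in% names(modifications)))
  n <- nchar(sequence)
  if (any(modifications$position < 1L | modifications$position > n)) {
    stop("modification position outside 1..", n)
  }
  if (anyDuplicated(modifications$position)) {
    stop("at most one modification per residue position")
  }
  if (any(!is.finite(modifications$mass_delta))) {
    stop("modification mass_delta must be finite")
  }
  modifications
}

#' Neutral monoisotopic mass of a (modified) peptide
#'
#' Sum of residue monoisotopic masses plus one water, plus the mass
#' deltas of any modifications. A hydroxylation is represented as
#' `mass_delta = HYDROXYLATION_DELTA` at the modified position, so a
#' hydroxylated peptide is exactly +15.994915 Da heavier than its base
#' peptide.
#'
#' @param sequence Peptide sequence (canonical residues).
#' @param modifications Optional data frame with columns `position`
#'   (1-based within the peptide) and `mass_delta` (Da).
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("G")  # 75.03203
#' @export
monoisotopic_mass <- function(sequence, modifications = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!canonical_ok(sequence)) {
    stop("empty sequence or non-canonical residue in '", sequence, "'")
  }
  mods <- validate_modifications(sequence, modifications)
  res <- strsplit(sequence, "")[[1]]
  sum(RESIDUE_MASSES[res]) + WATER_MASS + sum(mods$mass_delta)
}
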