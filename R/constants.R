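#' Physical constants and residue mass registries
#'
#' Monoisotopic masses used throughout the package. The monosaccharide
#' registry follows the one-letter nomenclature of the pGlyco search-engine
#' family: H = hexose, N = N-acetylhexosamine, F = deoxyhexose (fucose),
#' A = N-acetylneuraminic acid, G = N-glycolylneuraminic acid, X = xylose.
#' All registries are config-overridable through function arguments.
#'
#' @name constants
NULL

#' Mass of a proton in Da (monoisotopic).
#' @export
PROTON_MASS <- 1.00727646

#' Mass of water in Da (monoisotopic).
#' @export
WATER_MASS <- 18.0105646863

#' Mass offset of the 0,2X0 cross-ring fragment of the reducing-end HexNAc
#' (denoted `$`), relative to the naked peptide: composition C4H5NO.
#' Overridable wherever it is consumed.
#' @export
CROSSRING_MASS <- 83.03711

#' Monoisotopic residue mass of HexNAc, used for the b/y + HexNAc ion series.
#' @export
HEXNAC_MASS <- 203.07937

#' Monosaccharide residue-mass registry
#'
#' @param extra named numeric vector of additional or overriding one-letter
#'   codes (residue masses in Da).
#' @return named numeric vector of monoisotopic residue masses.
#' @export
monosaccharide_masses <- function(extra = NULL) {
  reg <- c(H = 162.05282, N = 203.07937, F = 146.05791,
           A = 291.09542, G = 307.09033, X = 132.04226)
  if (!is.null(extra)) {
    stopifnot(is.numeric(extra), !is.null(names(extra)), all(extra > 0),
              all(nchar(names(extra)) == 1L))
    reg[names(extra)] <- extra
  }
  if (anyDuplicated(names(reg)) > 0L)
    stop("duplicate monosaccharide codes in registry")
  reg
}

#' Amino-acid residue-mass registry
#'
#' Standard monoisotopic residue masses for the 20 amino acids plus `J`,
#' the glycosylated asparagine marker (mass of Asn; the glycan mass is
#' carried separately).
#'
#' @return named numeric vector of monoisotopic residue masses in Da.
#' @export
amino_acid_masses <- function() {
  c(G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
    T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
    N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
    E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
    R = 156.10111, Y = 163.06333, W = 186.07931, J = 114.04293)
}
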