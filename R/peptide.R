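#' Peptide masses and theoretical fragment m/z
#'
#' Peptides are amino-acid strings where `J` marks the glycosylated
#' asparagine (N-glycosylation sequon). Modifications are positional mass
#' deltas. The glycan mass is carried separately and enters only precursor
#' and Y-ion masses.
#'
#' @name peptide
NULL

mods_deltas <- function(mods, n) {
  # mods: NULL, or data.frame(position, delta); returns per-residue delta vector
  d <- numeric(n)
  if (is.null(mods) || NROW(mods) == 0L) return(d)
  stopifnot(all(c("position", "delta") %in% names(mods)))
  for (i in seq_len(NROW(mods))) {
    p <- mods$position[i]
    stopifnot(p >= 1L, p <= n)
    d[p] <- d[p] + mods$delta[i]
  }
  d
}

#' Monoisotopic mass of a (naked) peptide
#'
#' @param peptide amino-acid string (may contain `J`).
#' @param mods optional data.frame with columns `position` and `delta` (Da).
#' @return neutral monoisotopic mass in Da, glycan excluded.
#' @export
peptide_mass <- function(peptide, mods = NULL) {
  aa <- strsplit(peptide, "", fixed = TRUE)[[1]]
  masses <- amino_acid_masses()
  if (!all(aa %in% names(masses)))
    stop("unknown amino acid in ", peptide)
  sum(masses[aa]) + WATER_MASS + sum(mods_deltas(mods, length(aa)))
}

#' Precursor m/z of a glycopeptide
#'
#' @param peptide amino-acid string with `J` glycosite marker.
#' @param glycan glycan structure (string or `glycan_struct`), composition
#'   key, or numeric glycan mass in Da.
#' @param charge precursor charge state.
#' @param mods optional modification data.frame.
#' @return m/z in Da.
#' @export
glycopeptide_mz <- function(peptide, glycan, charge, mods = NULL) {
  gm <- if (is.numeric(glycan)) glycan else glycan_mass(glycan)
  (peptide_mass(peptide, mods) + gm + charge * PROTON_MASS) / charge
}

#' Theoretical peptide-backbone fragment m/z
#'
#' Supports the b/y series and their glycan-retaining variants: `b-N1`/`y-N1`
#' (one HexNAc attached) and `b$`/`y$` (cross-ring fragment of the
#' reducing-end HexNAc). The HexNAc/cross-ring offsets apply only to
#' fragments containing the glycosite.
#'
#' @param peptide amino-acid string with `J` marker.
#' @param type one of `"b"`, `"y"`, `"b-N1"`, `"y-N1"`, `"b$"`, `"y$"`.
#' @param ordinal fragment ordinal (1 to length-1).
#' @param charge fragment charge.
#' @param mods optional modification data.frame.
#' @param crossring_mass cross-ring fragment mass offset in Da.
#' @param require_glycosite if `TRUE` (default), glycan-retaining variants
#'   of fragments not containing the glycosite return `NA`; decoy
#'   generation disables the check to preserve transition counts.
#' @return m/z in Da, or `NA` if the variant does not apply (fragment does
#'   not contain the glycosite).
#' @export
backbone_fragment_mz <- function(peptide, type, ordinal, charge, mods = NULL,
                                 crossring_mass = CROSSRING_MASS,
                                 require_glycosite = TRUE) {
  aa <- strsplit(peptide, "", fixed = TRUE)[[1]]
  n <- length(aa)
  stopifnot(ordinal >= 1L, ordinal <= n - 1L)
  masses <- amino_acid_masses()
  deltas <- mods_deltas(mods, n)
  nterm <- startsWith(type, "b")
  idx <- if (nterm) seq_len(ordinal) else seq.int(n - ordinal + 1L, n)
  frag <- sum(masses[aa[idx]]) + sum(deltas[idx]) + if (nterm) 0 else WATER_MASS
  offset <- if (grepl("-N1$", type)) HEXNAC_MASS else if (grepl("\\$$", type)) crossring_mass else 0
  if (require_glycosite && offset > 0 && !any(aa[idx] == "J")) return(NA_real_)
  (frag + charge * PROTON_MASS) / charge
}

#' Theoretical Y-ion m/z
#'
#' @param pep_mass neutral peptide mass in Da (see [peptide_mass()]).
#' @param glycan_frag_mass mass of the retained glycan portion in Da
#'   (0 for Y0).
#' @param charge fragment charge.
#' @return m/z in Da.
#' @export
y_ion_mz <- function(pep_mass, glycan_frag_mass, charge) {
  (pep_mass + glycan_frag_mass + charge * PROTON_MASS) / charge
}
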