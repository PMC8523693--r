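#' Decoy library generation
#'
#' Target-decoy competition in two dimensions requires three decoy classes:
#' peptide decoys (reversed peptide, target glycan), glycan decoys (target
#' peptide, mass-shifted Y ions), and both decoys. Appending one of each
#' per target makes the combined library four times the target size.
#'
#' @name decoys
NULL

#' Reverse a peptide sequence, keeping C-terminal K/R in place
#'
#' The glycosite marker `J` moves with its residue; modification positions
#' are remapped accordingly.
#'
#' @param peptide amino-acid string.
#' @param mods optional modification data.frame.
#' @return list with `peptide` (string) and `mods` (remapped data.frame).
#' @export
reverse_peptide <- function(peptide, mods = NULL) {
  aa <- strsplit(peptide, "", fixed = TRUE)[[1]]
  n <- length(aa)
  if (n == 0L) stop("empty peptide")
  m <- if (aa[n] %in% c("K", "R")) n - 1L else n
  map <- c(rev(seq_len(m)), if (m < n) seq.int(m + 1L, n))
  out_aa <- aa[map]
  out_mods <- NULL
  if (!is.null(mods) && NROW(mods)) {
    out_mods <- mods
    out_mods$position <- match(mods$position, map)
  }
  list(peptide = paste(out_aa, collapse = ""), mods = out_mods)
}

shuffle_interior <- function(peptide, rng_unused = NULL) {
  aa <- strsplit(peptide, "", fixed = TRUE)[[1]]
  n <- length(aa)
  m <- if (aa[n] %in% c("K", "R")) n - 1L else n
  perm <- sample.int(m)
  list(map = c(perm, if (m < n) seq.int(m + 1L, n)),
       peptide = paste(aa[c(perm, if (m < n) seq.int(m + 1L, n))], collapse = ""))
}

decoy_peptide_for <- function(peptide, mods, taken, max_retry = 20L) {
  cand <- reverse_peptide(peptide, mods)
  if (!(cand$peptide %in% taken) && cand$peptide != peptide) return(cand)
  aa <- strsplit(peptide, "", fixed = TRUE)[[1]]
  n <- length(aa)
  for (i in seq_len(max_retry)) {
    sh <- shuffle_interior(peptide)
    if (!(sh$peptide %in% taken) && sh$peptide != peptide) {
      out_mods <- NULL
      if (!is.null(mods) && NROW(mods)) {
        out_mods <- mods
        out_mods$position <- match(mods$position, sh$map)
      }
      return(list(peptide = sh$peptide, mods = out_mods))
    }
  }
  NULL
}

recompute_backbone_mz <- function(transitions, peptide, mods,
                                  crossring_mass = CROSSRING_MASS) {
  idx <- which(transitions$Part == "peptide")
  for (i in idx) {
    transitions$ProductMz[i] <- backbone_fragment_mz(
      peptide, transitions$FragmentType[i], transitions$FragmentSeriesNumber[i],
      transitions$FragmentCharge[i], mods, crossring_mass,
      require_glycosite = FALSE)
  }
  transitions
}

#' Generate a glycan decoy transition list
#'
#' Each Y-ion m/z except Y0 and the cross-ring fragment is shifted by an
#' independent uniform draw in `[1, 30)` Da on the singly-charged fragment
#' mass (divided by charge for multiply charged ions); peptide-part
#' transitions and the precursor m/z are unchanged.
#'
#' @param transitions transition data.frame of one entry.
#' @param shift_range numeric length-2 mass-shift range in Da.
#' @return shifted transition data.frame.
#' @export
glycan_decoy_transitions <- function(transitions, shift_range = c(1, 30)) {
  idx <- which(transitions$Part == "glycan" &
                 !(transitions$FragmentComposition %in% c("0", "$")))
  if (length(idx)) {
    shifts <- stats::runif(length(idx), shift_range[1], shift_range[2])
    transitions$ProductMz[idx] <- transitions$ProductMz[idx] +
      shifts / transitions$FragmentCharge[idx]
  }
  transitions
}

#' Build the combined target + decoy library
#'
#' Appends, per target entry, one peptide decoy (reversed peptide, target
#' glycan), one glycan decoy (Y-ion mass shifts) and one both decoy, so the
#' combined library is four times the size of the target library. Decoy
#' RTs and precursor m/z equal their targets so decoys compete in the same
#' extraction windows. Fully deterministic under `seed`.
#'
#' @param lib target `glyco_library`.
#' @param seed integer seed.
#' @param shift_range glycan decoy mass-shift range in Da.
#' @return combined `glyco_library` with `IsDecoy`/`DecoyType` set.
#' @export
build_decoy_library <- function(lib, seed = 1L, shift_range = c(1, 30)) {
  stopifnot(inherits(lib, "glyco_library"))
  prec <- lib$precursors
  if (!nrow(prec)) return(lib)
  if (any(prec$IsDecoy)) stop("target library already contains decoys")
  set.seed(seed)
  taken <- unique(prec$Peptide)
  tsplit <- split(lib$transitions, lib$transitions$PrecursorId)
  out_p <- list(lib$precursors); out_t <- list(lib$transitions)
  skipped <- 0L
  for (i in seq_len(nrow(prec))) {
    p <- prec[i, ]
    tr <- tsplit[[p$PrecursorId]]
    mods <- parse_mods(p$Modifications)
    dec <- decoy_peptide_for(p$Peptide, mods, taken)
    if (is.null(dec)) { skipped <- skipped + 1L; next }
    for (dtype in c("peptide", "glycan", "both")) {
      dp <- p
      dtr <- tr
      if (dtype %in% c("peptide", "both")) {
        dp$Peptide <- dec$peptide
        dp$Modifications <- format_mods(dec$mods)
        dtr <- recompute_backbone_mz(dtr, dec$peptide, dec$mods)
      }
      if (dtype %in% c("glycan", "both")) {
        dtr <- glycan_decoy_transitions(dtr, shift_range)
      }
      dp$IsDecoy <- TRUE
      dp$DecoyType <- dtype
      dp$PrecursorId <- paste0("DECOY_", dtype, "_", p$PrecursorId)
      dtr$PrecursorId <- dp$PrecursorId
      out_p[[length(out_p) + 1L]] <- dp
      out_t[[length(out_t) + 1L]] <- dtr
    }
  }
  if (skipped > 0L)
    warning(skipped, " target entr", if (skipped == 1L) "y" else "ies",
            " skipped: no collision-free decoy peptide found")
  glyco_library(do.call(rbind, out_p), do.call(rbind, out_t))
}

#' Decoy identification transitions for glycoform scoring
#'
#' Replaces the peptide with a random same-length sequence of the 20 amino
#' acids (glycosite marker and PTMs kept at their positions), resampled
#' until the decoy peptide mass differs from the target by at least
#' `min_mass_diff` Da, and builds Y-series identification transitions from
#' the decoy peptide mass and the target glycan fragments.
#'
#' @param peptide target peptide with `J` marker.
#' @param mods modification data.frame or string.
#' @param fragment_keys character vector of Y-composition keys to emit.
#' @param charges fragment charge states.
#' @param min_mass_diff minimum peptide mass difference in Da (default 1).
#' @param max_retry resampling budget.
#' @param registry monosaccharide registry.
#' @return list with `peptide` (decoy sequence) and `transitions`
#'   (data.frame of decoy identification transitions).
#' @export
glycoform_decoy_transitions <- function(peptide, mods, fragment_keys,
                                        charges = 1:2, min_mass_diff = 1,
                                        max_retry = 100L,
                                        registry = monosaccharide_masses()) {
  if (is.character(mods)) mods <- parse_mods(mods)
  aa <- strsplit(peptide, "", fixed = TRUE)[[1]]
  pool <- setdiff(names(amino_acid_masses()), c("J", "I"))
  tmass <- peptide_mass(peptide, mods)
  for (i in seq_len(max_retry)) {
    daa <- sample(pool, length(aa), replace = TRUE)
    daa[aa == "J"] <- "J"
    dpep <- paste(daa, collapse = "")
    dmass <- peptide_mass(dpep, mods)
    if (abs(dmass - tmass) >= min_mass_diff) {
      gm <- fragment_composition_mass(fragment_keys, registry = registry)
      grid <- expand.grid(k = seq_along(fragment_keys), z = charges)
      tr <- data.frame(
        FragmentType = "Y", FragmentSeriesNumber = NA_integer_,
        FragmentComposition = fragment_keys[grid$k],
        FragmentCharge = grid$z,
        ProductMz = y_ion_mz(dmass, gm[grid$k], grid$z),
        Part = "glycan", IsDecoy = TRUE, stringsAsFactors = FALSE)
      return(list(peptide = dpep, transitions = tr))
    }
  }
  stop("could not generate a decoy peptide with mass difference >= ",
       min_mass_diff, " Da for ", peptide)
}
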