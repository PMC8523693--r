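#' Semi-empirical spectral library generation
#'
#' Unobserved peptide-glycan combinations are predicted by fragment
#' swapping: the peptide-part fragments of a target (P, G, n+) come from
#' observed spectra of peptide P carrying glycans near G, and the
#' glycan-part (Y) fragments from observed spectra of glycan G on peptides
#' near P, each merged by the consensus rules of library building and
#' scaled to the mean peptide-to-glycan sum-intensity ratio. Retention
#' times are Gaussian-distance-weighted means over the peptide-sharing
#' neighbors, charge states pooled.
#'
#' Peptides are vectorized to amino-acid composition (20 counts); glycans
#' to monosaccharide composition (Hex, HexNAc, NeuAc, Fuc counts).
#'
#' @name semiempirical
NULL

#' Amino-acid composition vector of a peptide
#' @param peptide amino-acid string (`J` counted as N).
#' @return integer vector of length 20 (alphabetical amino-acid order).
#' @export
peptide_vector <- function(peptide) {
  aas <- sort(setdiff(names(amino_acid_masses()), "J"))
  aa <- strsplit(gsub("J", "N", peptide), "", fixed = TRUE)[[1]]
  tab <- table(factor(aa, levels = aas))
  stats::setNames(as.integer(tab), aas)
}

#' Monosaccharide composition vector of a glycan
#' @param glycan glycan structure text, `glycan_struct`, or composition key.
#' @return integer vector of counts of Hex, HexNAc, NeuAc, Fuc.
#' @export
glycan_vector <- function(glycan) {
  counts <- if (inherits(glycan, "glycan_struct") || grepl("^\\(", glycan)) {
    glycan_composition(glycan)
  } else {
    parse_composition_key(glycan)
  }
  c(Hex = unname(counts["H"]), HexNAc = unname(counts["N"]),
    NeuAc = unname(counts["A"]), Fuc = unname(counts["F"]))
}

euclid <- function(a, b) sqrt(sum((a - b)^2))

#' Find KNN neighbor sets for a target glycopeptide precursor
#'
#' `S_P` holds library entries with the target peptide and charge, `S_G`
#' entries with the target glycan composition and charge (the query entry
#' itself excluded). `S_Pk` is the k nearest of `S_P` by Euclidean
#' distance between glycan vectors; `S_Gk` the k nearest of `S_G` by
#' peptide-vector distance. Distance ties at rank k are resolved by
#' library order. When either candidate set holds fewer than k entries
#' the precursor is reported unpredictable.
#'
#' @param peptide,glycan,charge target coordinates (`glycan` a structure
#'   string or composition key).
#' @param library a `glyco_library`.
#' @param k number of neighbors (default 3).
#' @param exclude_id precursor id excluded from the candidate sets (for
#'   leave-one-out validation).
#' @param charge_pooled_rt if `TRUE` (default), the RT neighbor set `S_P`
#'   ignores charge states.
#' @return a `neighbor_set` list with elements `s_pk`, `s_gk` (precursor
#'   data.frames), `d_pk`, `d_gk` (distances), `s_p_rt`, `d_rt` (charge-
#'   pooled RT neighbors), and `ok`; or `ok = FALSE` with a `reason`.
#' @export
find_neighbors <- function(peptide, glycan, charge, library, k = 3L,
                           exclude_id = NULL, charge_pooled_rt = TRUE) {
  prec <- library$precursors[!library$precursors$IsDecoy, , drop = FALSE]
  if (!is.null(exclude_id)) prec <- prec[prec$PrecursorId != exclude_id, , drop = FALSE]
  comp <- if (grepl("^\\(", glycan)) composition_key(glycan_composition(glycan)) else glycan
  gv <- glycan_vector(comp)
  pv <- peptide_vector(peptide)
  s_p <- prec[prec$Peptide == peptide & prec$Charge == charge, , drop = FALSE]
  s_g <- prec[prec$GlycanComposition == comp & prec$Charge == charge, , drop = FALSE]
  if (nrow(s_p) < k || nrow(s_g) < k) {
    return(structure(list(ok = FALSE,
                          reason = sprintf("insufficient neighbors (|S_P| = %d, |S_G| = %d, k = %d)",
                                           nrow(s_p), nrow(s_g), k)),
                     class = "neighbor_set"))
  }
  d_p <- vapply(s_p$GlycanComposition, function(x) euclid(glycan_vector(x), gv), 0)
  d_g <- vapply(s_g$Peptide, function(x) euclid(peptide_vector(x), pv), 0)
  top <- function(d) utils::head(order(d), k)  # order() breaks ties by index
  ip <- top(d_p); ig <- top(d_g)
  out <- list(ok = TRUE,
              s_pk = s_p[ip, , drop = FALSE], d_pk = unname(d_p[ip]),
              s_gk = s_g[ig, , drop = FALSE], d_gk = unname(d_g[ig]))
  if (charge_pooled_rt) {
    s_p_all <- prec[prec$Peptide == peptide, , drop = FALSE]
    d_all <- vapply(s_p_all$GlycanComposition, function(x) euclid(glycan_vector(x), gv), 0)
    irt <- utils::head(order(d_all), min(k, nrow(s_p_all)))
    out$s_p_rt <- s_p_all[irt, , drop = FALSE]
    out$d_rt <- unname(d_all[irt])
  } else {
    out$s_p_rt <- out$s_pk
    out$d_rt <- out$d_pk
  }
  structure(out, class = "neighbor_set")
}

#' Gaussian distance weights for RT prediction
#'
#' `w_i = exp(-d_i^2 / (2 sigma^2)) / sqrt(2 pi sigma^2)` with
#' `sigma^2 = mean(d_i^2)`; when all distances are zero the weights are
#' uniform.
#'
#' @param d numeric distance vector.
#' @return weight vector (unnormalized).
#' @export
knn_rt_weights <- function(d) {
  sigma2 <- mean(d^2)
  if (sigma2 == 0) return(rep(1, length(d)))
  exp(-d^2 / (2 * sigma2)) / sqrt(2 * pi * sigma2)
}

#' Predict the retention time of a glycopeptide
#'
#' Weighted mean RT over the peptide-sharing neighbors, charge states
#' pooled, with Gaussian weights in the glycan-vector distance.
#'
#' @param neighbors a `neighbor_set` from [find_neighbors()].
#' @return predicted RT in minutes.
#' @export
predict_rt <- function(neighbors) {
  stopifnot(isTRUE(neighbors$ok))
  w <- knn_rt_weights(neighbors$d_rt)
  sum(w * neighbors$s_p_rt$NormalizedRetentionTime) / sum(w)
}

part_ratio <- function(transitions) {
  pep <- sum(transitions$LibraryIntensity[transitions$Part == "peptide"])
  gly <- sum(transitions$LibraryIntensity[transitions$Part == "glycan"])
  if (gly == 0) return(NA_real_)
  pep / gly
}

#' Predict the MS/MS spectrum of a glycopeptide precursor
#'
#' Peptide-part fragments are the consensus of the `S_Pk` spectra and
#' glycan-part (Y) fragments the consensus of the `S_Gk` spectra (same
#' consensus rules as library building, weighted by entry scores); the two
#' parts are scaled so that the peptide-to-glycan sum-intensity ratio
#' equals the mean ratio over the `S_Pk` and `S_Gk` spectra. Fragment m/z
#' values are recomputed for the target peptide and glycan composition.
#'
#' @param peptide,mods,glycan,charge target coordinates (`glycan` a
#'   structure string; its composition determines the Y-ion masses).
#' @param neighbors a `neighbor_set`.
#' @param library the `glyco_library` supplying the neighbor transitions.
#' @param registry monosaccharide registry.
#' @param crossring_mass cross-ring offset in Da.
#' @return transition data.frame of the predicted entry, or `NULL` when a
#'   consensus part is empty.
#' @export
predict_spectrum <- function(peptide, mods, glycan, charge, neighbors, library,
                             registry = monosaccharide_masses(),
                             crossring_mass = CROSSRING_MASS) {
  stopifnot(isTRUE(neighbors$ok))
  if (is.character(mods)) mods <- parse_mods(mods)
  trans <- library$transitions
  get_part <- function(entries, part) {
    lapply(entries$PrecursorId, function(id) {
      tr <- trans[trans$PrecursorId == id & trans$Part == part, , drop = FALSE]
      tr$PrecursorId <- NULL
      tr
    })
  }
  pep_reps <- get_part(neighbors$s_pk, "peptide")
  gly_reps <- get_part(neighbors$s_gk, "glycan")
  if (any(vapply(pep_reps, nrow, 0L) == 0L) || any(vapply(gly_reps, nrow, 0L) == 0L))
    return(NULL)
  pep_cons <- build_consensus(pep_reps, neighbors$s_pk$SumScore)$transitions
  gly_cons <- build_consensus(gly_reps, neighbors$s_gk$SumScore)$transitions
  if (!nrow(pep_cons) || !nrow(gly_cons)) return(NULL)
  ratios <- c(
    vapply(neighbors$s_pk$PrecursorId, function(id)
      part_ratio(trans[trans$PrecursorId == id, , drop = FALSE]), 0),
    vapply(neighbors$s_gk$PrecursorId, function(id)
      part_ratio(trans[trans$PrecursorId == id, , drop = FALSE]), 0))
  r <- mean(ratios, na.rm = TRUE)
  # recompute m/z for the target coordinates
  pm <- peptide_mass(peptide, mods)
  pep_cons$ProductMz <- mapply(function(ty, o, z)
    backbone_fragment_mz(peptide, ty, o, z, mods, crossring_mass),
    pep_cons$FragmentType, pep_cons$FragmentSeriesNumber, pep_cons$FragmentCharge)
  pep_cons <- pep_cons[!is.na(pep_cons$ProductMz), , drop = FALSE]
  gm <- fragment_composition_mass(gly_cons$FragmentComposition, crossring_mass, registry)
  gly_cons$ProductMz <- y_ion_mz(pm, gm, gly_cons$FragmentCharge)
  if (!nrow(pep_cons)) return(NULL)
  # scale parts to the target ratio r (glycan part to unit sum)
  sg <- sum(gly_cons$LibraryIntensity)
  sp <- sum(pep_cons$LibraryIntensity)
  if (sg == 0 || sp == 0 || !is.finite(r)) return(NULL)
  gly_cons$LibraryIntensity <- gly_cons$LibraryIntensity / sg
  pep_cons$LibraryIntensity <- pep_cons$LibraryIntensity / sp * r
  out <- rbind(pep_cons, gly_cons)
  out <- out[order(out$ProductMz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

predict_entry <- function(peptide, mods, glycan, charge, library, k = 3L,
                          exclude_id = NULL, scan_range = c(200, 2000),
                          scheme = default_isolation_scheme(),
                          registry = monosaccharide_masses()) {
  nb <- find_neighbors(peptide, glycan, charge, library, k = k,
                       exclude_id = exclude_id)
  if (!isTRUE(nb$ok)) return(list(ok = FALSE, reason = nb$reason))
  if (is.character(mods)) mods <- parse_mods(mods)
  struct <- if (grepl("^\\(", glycan)) serialize_glycan(parse_glycan(glycan, registry))
            else nb$s_gk$GlycanStructure[1]
  tr <- predict_spectrum(peptide, mods, struct, charge, nb, library,
                         registry = registry)
  if (is.null(tr)) return(list(ok = FALSE, reason = "empty consensus part"))
  pmz <- glycopeptide_mz(peptide, struct, charge, mods)
  tr <- filter_transitions(tr, pmz, scan_range, scheme)
  if (is.null(tr)) return(list(ok = FALSE, reason = "failed transition filters"))
  pid <- precursor_id(peptide, mods, struct, charge)
  tr$PrecursorId <- pid
  prec <- data.frame(
    PrecursorId = pid, Peptide = peptide, Modifications = format_mods(mods),
    GlycanStructure = struct,
    GlycanComposition = composition_key(glycan_composition(struct, registry)),
    Charge = as.integer(charge), PrecursorMz = pmz,
    NormalizedRetentionTime = predict_rt(nb),
    ReplicateCount = 0L, SumScore = 0,
    Provenance = "semi-empirical", IsDecoy = FALSE, DecoyType = "",
    stringsAsFactors = FALSE)
  list(ok = TRUE, precursor = prec, transitions = tr)
}

#' Leave-one-out cross-validation of semi-empirical prediction
#'
#' Pulls each target precursor out of the library, predicts it from the
#' remaining entries, and compares the predicted spectrum (dot product on
#' intensities aligned by annotation) and RT against the held-out entry.
#'
#' @param library a `glyco_library`.
#' @param k number of neighbors.
#' @return list with `results` (per-precursor data.frame: `precursor_id`,
#'   `dp`, `rt_error`) and `summary` (`n_predicted`, `median_dp`,
#'   `rt_iqr`, `rt_pearson_r`).
#' @export
cross_validate <- function(library, k = 3L) {
  prec <- library$precursors[!library$precursors$IsDecoy, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(prec))) {
    p <- prec[i, ]
    pr <- predict_entry(p$Peptide, p$Modifications, p$GlycanStructure, p$Charge,
                        library, k = k, exclude_id = p$PrecursorId)
    if (!isTRUE(pr$ok)) next
    obs <- library$transitions[library$transitions$PrecursorId == p$PrecursorId, , drop = FALSE]
    keys <- union(transition_key(obs), transition_key(pr$transitions))
    v_obs <- numeric(length(keys)); v_prd <- numeric(length(keys))
    v_obs[match(transition_key(obs), keys)] <- obs$LibraryIntensity
    v_prd[match(transition_key(pr$transitions), keys)] <- pr$transitions$LibraryIntensity
    rows[[length(rows) + 1L]] <- data.frame(
      precursor_id = p$PrecursorId,
      dp = cosine_dp(v_obs, v_prd),
      rt_error = pr$precursor$NormalizedRetentionTime - p$NormalizedRetentionTime,
      rt_obs = p$NormalizedRetentionTime,
      rt_pred = pr$precursor$NormalizedRetentionTime,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(list(results = data.frame(), summary = list(n_predicted = 0L)))
  }
  res <- do.call(rbind, rows)
  list(results = res,
       summary = list(
         n_predicted = nrow(res),
         median_dp = stats::median(res$dp),
         rt_iqr = stats::IQR(res$rt_error),
         rt_pearson_r = if (nrow(res) > 2 && stats::sd(res$rt_pred) > 0 &&
                              stats::sd(res$rt_obs) > 0)
           stats::cor(res$rt_obs, res$rt_pred) else NA_real_))
}

#' Extend a library with semi-empirical entries
#'
#' Predictions are generated only for the listed peptide-glycan
#' combinations absent from the base library; base entries always take
#' precedence and predicted entries carry `Provenance = "semi-empirical"`.
#'
#' @param library base `glyco_library`.
#' @param combinations data.frame with columns `Peptide`, `Modifications`,
#'   `GlycanComposition`.
#' @param k number of neighbors.
#' @param charges charge states to attempt per combination (default: all
#'   charges under which the peptide appears in the base library).
#' @return extended `glyco_library`.
#' @export
extend_library <- function(library, combinations, k = 3L, charges = NULL) {
  if (!NROW(combinations)) return(library)
  prec <- library$precursors[!library$precursors$IsDecoy, , drop = FALSE]
  have <- unique(paste(prec$Peptide, prec$Modifications, prec$GlycanComposition))
  new_p <- list(); new_t <- list()
  for (i in seq_len(NROW(combinations))) {
    cb <- combinations[i, ]
    mods_str <- if ("Modifications" %in% names(cb)) cb$Modifications else ""
    if (is.na(mods_str)) mods_str <- ""
    key <- paste(cb$Peptide, mods_str, cb$GlycanComposition)
    if (key %in% have) next
    zs <- charges
    if (is.null(zs)) zs <- sort(unique(prec$Charge[prec$Peptide == cb$Peptide]))
    for (z in zs) {
      pr <- predict_entry(cb$Peptide, mods_str, cb$GlycanComposition, z,
                          library, k = k)
      if (!isTRUE(pr$ok)) next
      if (pr$precursor$PrecursorId %in% prec$PrecursorId) next
      new_p[[length(new_p) + 1L]] <- pr$precursor
      new_t[[length(new_t) + 1L]] <- pr$transitions
    }
  }
  if (!length(new_p)) return(library)
  add <- glyco_library(do.call(rbind, new_p), do.call(rbind, new_t))
  merge_libraries(add, library)  # later library (base) wins on duplicates
}
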