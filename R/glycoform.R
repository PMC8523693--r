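#' Glycoform inference in wide isolation windows
#'
#' Glycopeptides sharing a peptide sequence but carrying different glycans
#' (glycoforms) can be co-isolated in a wide DIA window and share most of
#' their fragment signal. Inference proceeds in four steps: (i) collect
#' candidate background glycoforms from a glycan database, restricted to
#' the target's isolation window and ranked by Y-fragment Jaccard
#' similarity; (ii) generate in-silico Y-ion identification transitions
#' for all hypotheses; (iii) score extracted transition chromatograms
#' against decoy transitions to obtain per-transition PEPs; (iv) integrate
#' MS1, MS2-precursor and transition evidence into per-hypothesis
#' posteriors with a Bayesian hierarchical model, aggregate posteriors by
#' glycan composition, and derive glycoform-level q-values.
#'
#' @name glycoform_inference
NULL

#' Prepare a glycan database for repeated background queries
#'
#' Parses, canonicalizes and deduplicates the structures once, and
#' precomputes per structure its mass, composition key and theoretical
#' Y-fragment set (the expensive part of background-glycoform selection).
#'
#' @param structures character vector of glycan structure strings.
#' @param registry monosaccharide registry.
#' @return an object of class `prepared_glycan_db`.
#' @export
prepare_glycan_db <- function(structures, registry = monosaccharide_masses()) {
  structs <- unique(vapply(structures, function(g)
    serialize_glycan(parse_glycan(g, registry)), "", USE.NAMES = FALSE))
  fsets <- lapply(structs, enumerate_y_fragments, registry = registry)
  structure(list(
    structs = structs,
    mass = vapply(structs, glycan_mass, 0, registry = registry, USE.NAMES = FALSE),
    comp = vapply(structs, function(s)
      composition_key(glycan_composition(s, registry)), "", USE.NAMES = FALSE),
    fsets = fsets,
    sig = vapply(fsets, y_fragment_signature, "")),
    class = "prepared_glycan_db")
}

#' @export
print.prepared_glycan_db <- function(x, ...) {
  cat("<prepared_glycan_db> ", length(x$structs), " structures, ",
      length(unique(x$comp)), " compositions\n", sep = "")
  invisible(x)
}

#' Select background glycoforms for a target precursor
#'
#' Candidates are database glycans whose precursor m/z (same peptide,
#' modifications and charge) falls inside the target's isolation window.
#' Isomeric structures with identical theoretical Y-fragment sets are
#' merged into one hypothesis; hypotheses are ranked by Jaccard similarity
#' to the target glycan (descending; ties resolved by canonical structure
#' string) and the top `n_bg` background hypotheses are kept. The target
#' glycan is always hypothesis 1.
#'
#' @param peptide,mods,glycan,charge target precursor coordinates.
#' @param glycan_db character vector of glycan structure strings, or a
#'   `prepared_glycan_db` (preferred for repeated queries).
#' @param scheme isolation scheme data.frame.
#' @param n_bg maximum number of background hypotheses (default 50).
#' @param registry monosaccharide registry.
#' @return list of hypotheses; each a list with `structures` (canonical
#'   strings of the merged isomer group), `composition`, `fragment_keys`,
#'   `precursor_mz` and `is_target`.
#' @export
select_background_glycoforms <- function(peptide, mods, glycan, charge,
                                         glycan_db,
                                         scheme = default_isolation_scheme(),
                                         n_bg = 50L,
                                         registry = monosaccharide_masses()) {
  if (is.character(mods)) mods <- parse_mods(mods)
  target_struct <- serialize_glycan(parse_glycan(glycan, registry))
  target_fs <- enumerate_y_fragments(target_struct, registry)
  pm <- peptide_mass(peptide, mods)
  target_mz <- (pm + glycan_mass(target_struct, registry) + charge * PROTON_MASS) / charge
  win <- window_of(target_mz, scheme)
  hyp_target <- list(structures = target_struct,
                     composition = composition_key(glycan_composition(target_struct, registry)),
                     fragment_keys = target_fs$keys,
                     precursor_mz = target_mz, is_target = TRUE)
  if (!inherits(glycan_db, "prepared_glycan_db")) {
    if (!length(glycan_db)) return(list(hyp_target))
    glycan_db <- prepare_glycan_db(glycan_db, registry)
  }
  mzs_all <- (pm + glycan_db$mass + charge * PROTON_MASS) / charge
  keep <- glycan_db$structs != target_struct
  if (!is.null(win)) keep <- keep & mzs_all >= win$lower & mzs_all <= win$upper
  # drop candidates indistinguishable from the target itself
  keep <- keep & glycan_db$sig != y_fragment_signature(target_fs)
  if (!any(keep)) return(list(hyp_target))
  idx <- which(keep)
  groups <- split(idx, glycan_db$sig[idx])
  hyps <- lapply(unname(groups), function(ii) {
    list(structures = sort(glycan_db$structs[ii]),
         composition = glycan_db$comp[ii[1]],
         fragment_keys = glycan_db$fsets[[ii[1]]]$keys,
         precursor_mz = mzs_all[ii[1]], is_target = FALSE)
  })
  jac <- vapply(hyps, function(h) {
    length(intersect(setdiff(h$fragment_keys, ""), setdiff(target_fs$keys, ""))) /
      length(union(setdiff(h$fragment_keys, ""), setdiff(target_fs$keys, "")))
  }, 0)
  first_struct <- vapply(hyps, function(h) h$structures[1], "")
  hyps <- hyps[order(-jac, first_struct)]
  c(list(hyp_target), utils::head(hyps, n_bg))
}

#' Generate identification transitions for a hypothesis set
#'
#' The union of theoretical Y ions over all hypotheses (in-silico, even for
#' fragments also observed experimentally), each mapped to the set of
#' hypotheses it can originate from, plus one unfragmented-precursor
#' transition per hypothesis (MS2 precursor detection).
#'
#' @param hypotheses list from [select_background_glycoforms()].
#' @param peptide,mods target peptide and modifications.
#' @param charges Y-ion charge states (default 1:3).
#' @param scan_range MS2 scan range in Da.
#' @param registry monosaccharide registry.
#' @return data.frame with `transition_id`, `type` (`"y_ion"` or
#'   `"precursor"`), `composition`, `charge`, `mz`, and a `hypotheses`
#'   list-column of originating hypothesis indices.
#' @export
generate_identification_transitions <- function(hypotheses, peptide, mods,
                                                charges = 1:3,
                                                scan_range = c(200, 2000),
                                                registry = monosaccharide_masses()) {
  if (is.character(mods)) mods <- parse_mods(mods)
  pm <- peptide_mass(peptide, mods)
  keys <- unique(unlist(lapply(hypotheses, `[[`, "fragment_keys")))
  member <- lapply(keys, function(k)
    which(vapply(hypotheses, function(h) k %in% h$fragment_keys, TRUE)))
  gmass <- vapply(keys, function(k)
    if (nzchar(k)) glycan_mass(parse_composition_key(k, registry), registry) else 0, 0)
  grid <- expand.grid(k = seq_along(keys), z = charges)
  mz <- y_ion_mz(pm, gmass[grid$k], grid$z)
  ok <- mz >= scan_range[1] & mz <= scan_range[2]
  ykey <- ifelse(nzchar(keys[grid$k]), keys[grid$k], "0")
  y_tab <- data.frame(
    transition_id = paste0("Y_", ykey, "_", grid$z)[ok],
    type = "y_ion",
    composition = ykey[ok],
    charge = grid$z[ok],
    mz = mz[ok],
    stringsAsFactors = FALSE)
  y_tab$hypotheses <- member[grid$k][ok]
  prec_tab <- data.frame(
    transition_id = paste0("PREC_", seq_along(hypotheses)),
    type = "precursor",
    composition = vapply(hypotheses, `[[`, "", "composition"),
    charge = NA_integer_,
    mz = vapply(hypotheses, `[[`, 0, "precursor_mz"),
    stringsAsFactors = FALSE)
  prec_tab$hypotheses <- as.list(seq_along(hypotheses))
  out <- rbind(y_tab, prec_tab)
  out[!duplicated(out$transition_id), , drop = FALSE]
}

#' Transition-level PEPs from target and decoy transition scores
#'
#' A univariate kernel-density mixture: the null density is estimated from
#' decoy-transition discriminant scores, the marginal from the target
#' transitions, and the null proportion by Storey's method on empirical
#' p-values against the decoys. `PEP(s) = pi0 f0(s) / f(s)`, clipped to
#' `[0, 1]` and monotonized (non-increasing in the score).
#'
#' @param scores discriminant scores of target transitions.
#' @param decoy_scores discriminant scores of decoy transitions.
#' @param lambda Storey tuning parameter.
#' @return PEP vector aligned with `scores`.
#' @export
transition_peps <- function(scores, decoy_scores, lambda = 0.4) {
  if (!length(decoy_scores)) stop("no decoy transition scores provided")
  pi0 <- storey_pi(scores, decoy_scores, lambda)
  rng <- range(c(scores, decoy_scores))
  bw <- stats::bw.nrd0(c(scores, decoy_scores))
  grid <- seq(rng[1] - 3 * bw, rng[2] + 3 * bw, length.out = 512)
  f0 <- stats::density(decoy_scores, bw = bw, from = grid[1],
                       to = grid[length(grid)], n = length(grid))$y
  f1 <- stats::density(scores, bw = bw, from = grid[1],
                       to = grid[length(grid)], n = length(grid))$y
  pep_grid <- pmin(1, pmax(0, pi0 * f0 / pmax(f1, 1e-12 * max(f1))))
  pep_grid <- rev(cummax(rev(pep_grid)))  # non-increasing in score
  stats::approx(grid, pep_grid, xout = scores, rule = 2)$y
}

#' Score identification transitions against their decoys
#'
#' Reduces per-transition chromatogram sub-scores to a scalar discriminant
#' (a linear discriminant of targets against decoys when several
#' sub-scores are given) and converts it to per-transition PEPs with
#' [transition_peps()].
#'
#' @param features data.frame of target-transition sub-scores (numeric
#'   columns only).
#' @param decoy_features data.frame of decoy-transition sub-scores (same
#'   columns).
#' @param lambda Storey tuning parameter.
#' @return list with `pep` (per target transition), `decoy_pep` and
#'   `score`/`decoy_score` (the discriminants).
#' @export
score_identification_transitions <- function(features, decoy_features,
                                             lambda = 0.4) {
  if (!NROW(decoy_features)) stop("no decoy transitions provided")
  X <- as.matrix(features)
  D <- as.matrix(decoy_features[, colnames(X), drop = FALSE])
  if (ncol(X) == 1L) {
    s <- X[, 1]; sd_ <- D[, 1]
  } else {
    grp <- factor(rep(c("t", "d"), c(nrow(X), nrow(D))))
    fit <- MASS::lda(rbind(X, D), grouping = grp)
    w <- fit$scaling[, 1]
    s <- drop(X %*% w); sd_ <- drop(D %*% w)
    if (mean(s) < mean(sd_)) { s <- -s; sd_ <- -sd_ }
  }
  list(pep = transition_peps(s, sd_, lambda),
       decoy_pep = transition_peps(sd_, sd_, lambda),
       score = s, decoy_score = sd_)
}

#' Bayesian hierarchical posterior over glycoform hypotheses
#'
#' Hypothesis 0 is incorrect peak-group detection; hypotheses 1..N are
#' glycoforms. Priors divide `1 - PEP_MS2` equally over the glycan
#' compositions present (and `PEP_MS2` to hypothesis 0); within one
#' composition the prior is split equally over its isomer-group
#' hypotheses. Precursor evidence combines the MS1 conditional (membership
#' of the m/z-tolerance set `M`) with per-hypothesis MS2 unfragmented
#' precursor conditionals; transition evidence multiplies per-transition
#' conditionals (`1 - PEP` for originating hypotheses, `PEP` otherwise).
#' All products accumulate in log space with a per-factor floor of 1e-12.
#'
#' @param hypotheses list from [select_background_glycoforms()].
#' @param pep_ms2 MS2 peak-group PEP (scalar).
#' @param pep_ms1 MS1 precursor PEP, or `NA` to skip MS1 evidence.
#' @param in_tolerance logical vector over hypotheses: precursor m/z within
#'   the MS1 tolerance window of the target precursor (set `M`).
#' @param pep_ms2_prec per-hypothesis MS2 unfragmented-precursor PEPs, or
#'   `NULL` to skip.
#' @param transitions data.frame from
#'   [generate_identification_transitions()] of `type == "y_ion"` rows (and
#'   optionally precursor rows already consumed via `pep_ms2_prec`), with a
#'   `pep` column of transition PEPs; `NULL` for no transition evidence.
#' @return data.frame with one row per hypothesis (index 0 first):
#'   `hypothesis`, `composition`, `is_target`, `prior`, `p_g` (precursor
#'   posterior) and `p_g_t` (transition-integrated posterior).
#' @export
bhm_posterior <- function(hypotheses, pep_ms2, pep_ms1 = NA_real_,
                          in_tolerance = NULL, pep_ms2_prec = NULL,
                          transitions = NULL) {
  nh <- length(hypotheses)
  stopifnot(nh >= 1L, pep_ms2 >= 0, pep_ms2 <= 1)
  comps <- vapply(hypotheses, `[[`, "", "composition")
  n_comp <- length(unique(comps))
  per_comp <- (1 - pep_ms2) / n_comp
  prior <- c(pep_ms2, per_comp / as.vector(table(comps)[comps]))
  floor_log <- function(p) log(pmax(p, 1e-12))
  # precursor-level conditionals, hypothesis 0 included (never in M)
  log_b <- numeric(nh + 1L)
  if (!is.na(pep_ms1)) {
    if (is.null(in_tolerance))
      stop("in_tolerance must accompany pep_ms1")
    inM <- c(FALSE, in_tolerance)
    log_b <- log_b + floor_log(ifelse(inM, 1 - pep_ms1, pep_ms1))
  }
  if (!is.null(pep_ms2_prec)) {
    stopifnot(length(pep_ms2_prec) == nh)
    for (k in seq_len(nh)) {
      is_k <- c(FALSE, seq_len(nh) == k)
      log_b <- log_b + floor_log(ifelse(is_k, 1 - pep_ms2_prec[k], pep_ms2_prec[k]))
    }
  }
  log_post <- log(pmax(prior, 1e-300)) + log_b
  p_g <- exp(log_post - max(log_post))
  p_g <- p_g / sum(p_g)
  log_t <- numeric(nh + 1L)
  if (!is.null(transitions) && nrow(transitions)) {
    stopifnot(!is.null(transitions$pep), !is.null(transitions$hypotheses))
    for (j in seq_len(nrow(transitions))) {
      member <- c(FALSE, seq_len(nh) %in% transitions$hypotheses[[j]])
      pj <- transitions$pep[j]
      log_t <- log_t + floor_log(ifelse(member, 1 - pj, pj))
    }
  }
  log_post_t <- log(pmax(p_g, 1e-300)) + log_t
  if (all(!is.finite(log_post_t)))
    stop("all glycoform likelihoods vanished (numerical degeneracy)")
  p_g_t <- exp(log_post_t - max(log_post_t))
  p_g_t <- p_g_t / sum(p_g_t)
  data.frame(
    hypothesis = 0:nh,
    composition = c(NA_character_, comps),
    is_target = c(FALSE, vapply(hypotheses, `[[`, TRUE, "is_target")),
    prior = prior, p_g = p_g, p_g_t = p_g_t,
    stringsAsFactors = FALSE)
}

#' Aggregate structure-level posteriors to composition-level PPs
#'
#' @param posterior data.frame from [bhm_posterior()].
#' @return data.frame with `composition` (`NA` for incorrect detection),
#'   `is_target` and `pp` (summed posterior probability).
#' @export
aggregate_composition_pp <- function(posterior) {
  key <- ifelse(is.na(posterior$composition), "\rA0", posterior$composition)
  pp <- tapply(posterior$p_g_t, key, sum)
  is_t <- tapply(posterior$is_target, key, any)
  out <- data.frame(composition = ifelse(names(pp) == "\rA0", NA_character_, names(pp)),
                    is_target = as.logical(is_t), pp = as.numeric(pp),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(-out$pp), , drop = FALSE]
}

#' Glycoform-level q-values for target peak groups
#'
#' The glycoform PEP of a peak group is `1 - PP` of its library glycan
#' composition; q-values are average PEPs over acceptance sets. Peak
#' groups whose best explanation is a background glycan are excluded from
#' target reporting upstream.
#'
#' @param pp vector of target-composition posterior probabilities, one per
#'   target peak group.
#' @return data.frame with `pep` and `q`.
#' @export
glycoform_qvalues <- function(pp) {
  pep <- pmin(1, pmax(0, 1 - pp))
  data.frame(pep = pep, q = pep_to_qvalue(pep))
}
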