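#' End-to-end analysis workflows
#'
#' Convenience orchestration joining the scoring, glycoform-inference and
#' benchmark-evaluation stages on synthetic (or schema-compatible real)
#' tables.
#'
#' @name pipeline
NULL

#' Run glycoform inference over an entrapment benchmark
#'
#' Pools all transition-level scores (identification transitions, MS2
#' unfragmented precursors and MS1 precursors) against the pooled decoy
#' transitions to estimate per-transition PEPs, then integrates each
#' entry's evidence with the Bayesian hierarchical model and derives
#' glycoform-level q-values over the evaluated peak groups.
#'
#' @param benchmark list from [simulate_entrapment_benchmark()].
#' @param pep_ms2 named vector of MS2 peak-group PEPs (from 2D scoring),
#'   indexed by entry id.
#' @param entry_ids entries to evaluate (default: names of `pep_ms2`).
#' @return data.frame with `entry_id`, `entrapment`, `pp` (posterior of
#'   the library glycan composition), `pep` and `q`.
#' @export
run_glycoform_inference <- function(benchmark, pep_ms2,
                                    entry_ids = names(pep_ms2)) {
  gf <- benchmark$glycoform[entry_ids]
  stopifnot(!any(vapply(gf, is.null, TRUE)))
  target_scores <- unlist(lapply(gf, function(x) c(x$transitions$score, x$ms1_score)))
  decoy_scores <- unlist(lapply(gf, function(x) c(x$decoy_transitions$score,
                                                  x$ms1_decoy_score)))
  n_per <- vapply(gf, function(x) nrow(x$transitions) + 1L, 0L)
  peps <- transition_peps(target_scores, decoy_scores)
  offsets <- c(0L, cumsum(n_per))
  ent_map <- benchmark$entries$entrapment[match(entry_ids, benchmark$entries$entry_id)]
  mz_map <- benchmark$entries$precursor_mz[match(entry_ids, benchmark$entries$entry_id)]
  out <- data.frame(entry_id = entry_ids, entrapment = ent_map,
                    pp = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(entry_ids)) {
    x <- gf[[i]]
    pe <- peps[(offsets[i] + 1L):offsets[i + 1L]]
    trans <- x$transitions
    trans$pep <- pe[seq_len(nrow(trans))]
    pep_ms1 <- pe[nrow(trans) + 1L]
    hyp_mz <- vapply(x$hypotheses, `[[`, 0, "precursor_mz")
    in_tol <- abs(hyp_mz - mz_map[i]) / mz_map[i] * 1e6 <= benchmark$ms1_tol_ppm
    y <- trans[trans$type == "y_ion", , drop = FALSE]
    prec <- trans[trans$type == "precursor", , drop = FALSE]
    prec_pep <- rep(NA_real_, length(x$hypotheses))
    prec_pep[vapply(prec$hypotheses, `[[`, 0L, 1L)] <- prec$pep
    post <- bhm_posterior(x$hypotheses, pep_ms2 = pep_ms2[[entry_ids[i]]],
                          pep_ms1 = pep_ms1, in_tolerance = in_tol,
                          pep_ms2_prec = prec_pep, transitions = y)
    comp_pp <- aggregate_composition_pp(post)
    lib_comp <- x$hypotheses[[1]]$composition
    out$pp[i] <- sum(comp_pp$pp[!is.na(comp_pp$composition) &
                                  comp_pp$composition == lib_comp])
  }
  qv <- glycoform_qvalues(out$pp)
  out$pep <- qv$pep
  out$q <- qv$q
  out
}

#' Entrapment percentage at a q-value cutoff
#'
#' @param q q-value vector of reported candidates.
#' @param entrapment logical entrapment flags.
#' @param cutoff q-value cutoff (default 0.01).
#' @return percentage (0-100) of entrapment hits among all hits passing
#'   the cutoff, with attributes `n_hits` and `n_entrapment`.
#' @export
entrapment_percentage <- function(q, entrapment, cutoff = 0.01) {
  hit <- q <= cutoff
  pct <- if (!any(hit)) 0 else 100 * sum(entrapment & hit) / sum(hit)
  structure(pct, n_hits = sum(hit), n_entrapment = sum(entrapment & hit))
}

#' Run the full glycan-entrapment benchmark
#'
#' Simulates the benchmark, scores peak groups with the 2D FDR workflow,
#' applies the 1% peak-group-level q-value filter, runs glycoform
#' inference on the survivors, and evaluates entrapment percentages with
#' and without glycoform inference.
#'
#' @param n_targets,separation,seed,... passed to
#'   [simulate_entrapment_benchmark()].
#' @param peakgroup_q peak-group-level q-value cutoff (default 0.01).
#' @param glycoform_q glycoform-level q-value cutoff (default 0.01).
#' @return list with `inference` (per-entry result data.frame),
#'   `pct_with_inference`, `pct_without_inference`, `n_reported` and the
#'   intermediate `scored` table.
#' @export
run_entrapment_benchmark <- function(n_targets = 2000L, separation = 3,
                                     seed = 1L, peakgroup_q = 0.01,
                                     glycoform_q = 0.01, ...) {
  bench <- simulate_entrapment_benchmark(n_targets = n_targets,
                                         separation = separation,
                                         seed = seed, ...)
  res <- score_peak_groups(bench$features, seed = seed)
  sc <- res$scores
  tgt <- sc[sc$label == "target" & sc$is_best, , drop = FALSE]
  pass <- tgt[!is.na(tgt$q_run) & tgt$q_run <= peakgroup_q, , drop = FALSE]
  ent_flag <- bench$entries$entrapment[match(pass$precursor_id,
                                             bench$entries$entry_id)]
  pct_without <- entrapment_percentage(rep(0, nrow(pass)), ent_flag, cutoff = 0)
  pep_ms2 <- stats::setNames(pass$pep_porg, pass$precursor_id)
  inf <- run_glycoform_inference(bench, pep_ms2)
  pct_with <- entrapment_percentage(inf$q, inf$entrapment, cutoff = glycoform_q)
  list(inference = inf, scored = sc,
       pct_with_inference = as.numeric(pct_with),
       pct_without_inference = as.numeric(pct_without),
       n_reported = attr(pct_with, "n_hits"),
       n_entrapment_reported = attr(pct_with, "n_entrapment"),
       n_peakgroup_pass = nrow(pass))
}
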