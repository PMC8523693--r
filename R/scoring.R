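#' Two-dimensional FDR for glycopeptide peak groups
#'
#' Candidate peak groups carry peptide-evidence and glycan-evidence
#' sub-scores and a label: `target`, `peptide_decoy`, `glycan_decoy` or
#' `both_decoy`. Semi-supervised learning turns each sub-score block into a
#' discriminant score (D-score); the joint distribution of the peptide and
#' glycan D-scores over the four label classes identifies a bivariate
#' four-groups mixture from which posterior error probabilities (PEP,
#' local FDR) for the peptide part, the glycan part, their intersection
#' and their union are computed, and q-values (global FDR) are derived as
#' averages of PEPs over acceptance sets.
#'
#' Feature tables use columns prefixed `pep_` (peptide-evidence sub-scores)
#' and `gly_` (glycan-evidence sub-scores), plus `peak_group_id`,
#' `precursor_id`, `glycopeptide_id`, `run_id`, `rt_apex`, `label`.
#'
#' @name scoring_2dfdr
NULL

PEAKGROUP_LABELS <- c("target", "peptide_decoy", "glycan_decoy", "both_decoy")

axis_matrix <- function(features, axis) {
  prefix <- if (axis == "peptide") "^pep_" else "^gly_"
  cols <- grep(prefix, names(features), value = TRUE)
  if (!length(cols)) stop("no sub-score columns with prefix ", prefix)
  as.matrix(features[cols])
}

rank_auc <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(0.5)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Target-decoy q-values from score competition
#'
#' `q(s) = #(decoys >= s) / #(targets >= s)`, monotonized from the top of
#' the score list downwards.
#'
#' @param target_scores,decoy_scores numeric score vectors (higher = better).
#' @return q-value per target score.
#' @export
td_qvalues <- function(target_scores, decoy_scores) {
  sd_sorted <- sort(decoy_scores)
  nd <- length(decoy_scores)
  o <- order(target_scores, decreasing = TRUE)
  s <- target_scores[o]
  n_ge_t <- seq_along(s)
  n_ge_d <- nd - findInterval(s, sd_sorted, left.open = TRUE)
  fdr <- pmin(1, n_ge_d / n_ge_t)
  q <- rev(cummin(rev(fdr)))  # q_i = min FDR over acceptance sets containing i
  out <- numeric(length(s))
  out[o] <- q
  out
}

standardize_by <- function(score, ref) {
  s <- stats::sd(ref)
  if (!is.finite(s) || s == 0) s <- 1
  (score - mean(ref)) / s
}

pseudo_labels <- function(label, axis) {
  if (axis == "peptide") {
    list(pos = label %in% c("target", "glycan_decoy"),
         neg = label %in% c("peptide_decoy", "both_decoy"))
  } else {
    list(pos = label %in% c("target", "peptide_decoy"),
         neg = label %in% c("glycan_decoy", "both_decoy"))
  }
}

#' Learn a discriminant score for one evidence axis
#'
#' Semi-supervised iterative reweighting in the PyProphet style. For the
#' peptide axis, target and glycan-decoy peak groups act as pseudo-targets
#' while peptide-decoy and both-decoy peak groups act as pseudo-decoys;
#' the glycan axis swaps the roles. The learner initializes with the best
#' single sub-score, alternates confident-positive selection (target-decoy
#' q below `train_fdr`) with linear discriminant refits, and scores each
#' peak group with a model trained on the other cross-validation folds.
#' Scores are standardized against the pseudo-decoy distribution and
#' oriented so pseudo-decoys score lower.
#'
#' @param features peak-group feature data.frame.
#' @param axis `"peptide"` or `"glycan"`.
#' @param seed integer seed (fold assignment is the only randomness).
#' @param n_iter reweighting iterations (default 10).
#' @param n_folds cross-validation folds (default 3).
#' @param train_fdr within-iteration pseudo-positive selection cutoff.
#' @param min_train minimum pseudo-targets and pseudo-decoys required.
#' @return numeric D-score vector, one per row of `features`.
#' @export
learn_d_scores <- function(features, axis = c("peptide", "glycan"), seed = 1L,
                           n_iter = 10L, n_folds = 3L, train_fdr = 0.01,
                           min_train = 200L) {
  axis <- match.arg(axis)
  X <- axis_matrix(features, axis)
  pl <- pseudo_labels(features$label, axis)
  if (sum(pl$pos) < min_train || sum(pl$neg) < min_train)
    stop("too few training peak groups on the ", axis, " axis (",
         sum(pl$pos), " pseudo-targets, ", sum(pl$neg), " pseudo-decoys; ",
         "need ", min_train, " each). A larger spectral library is required ",
         "for unbiased learning and FDR estimation.")
  set.seed(seed)
  fold <- sample(rep_len(seq_len(n_folds), nrow(X)))
  scores <- numeric(nrow(X))
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    Xt <- X[tr, , drop = FALSE]
    pos <- pl$pos[tr]; neg <- pl$neg[tr]
    # initialize with the best-separating single sub-score
    aucs <- apply(Xt, 2, rank_auc, positive = pos)
    j0 <- which.max(abs(aucs - 0.5))
    s <- Xt[, j0] * sign(aucs[j0] - 0.5)
    w <- NULL
    for (it in seq_len(n_iter)) {
      q <- td_qvalues(s[pos], s[neg])
      sel <- which(pos)[q <= train_fdr]
      if (length(sel) < 10L) sel <- which(pos)[order(-s[pos])[seq_len(min(50L, sum(pos)))]]
      idx <- c(sel, which(neg))
      grp <- factor(c(rep("pos", length(sel)), rep("neg", sum(neg))))
      fit <- tryCatch(MASS::lda(Xt[idx, , drop = FALSE], grouping = grp),
                      error = function(e) NULL)
      if (is.null(fit)) break
      w_new <- fit$scaling[, 1]
      s_new <- drop(Xt %*% w_new)
      if (mean(s_new[sel]) < mean(s_new[neg])) { w_new <- -w_new; s_new <- -s_new }
      w <- w_new
      s <- standardize_by(s_new, s_new[neg])
    }
    te <- !tr
    if (is.null(w)) {
      s_te <- X[te, j0] * sign(aucs[j0] - 0.5)
      scores[te] <- standardize_by(s_te, Xt[neg, j0] * sign(aucs[j0] - 0.5))
    } else {
      s_all_tr <- drop(Xt %*% w)
      s_te <- drop(X[te, , drop = FALSE] %*% w)
      scores[te] <- (s_te - mean(s_all_tr[neg])) /
        max(stats::sd(s_all_tr[neg]), .Machine$double.eps)
    }
  }
  # final orientation: pseudo-decoys must not out-score pseudo-targets
  if (mean(scores[pl$neg]) > mean(scores[pl$pos])) scores <- -scores
  scores
}

#' Combine peptide and glycan D-scores
#'
#' Linear discriminant analysis of targets against all three decoy classes
#' on the (peptide, glycan) D-score pair; falls back to equal weights with
#' a warning when the within-class covariance is degenerate. The combined
#' score is standardized against the decoys and oriented target-high.
#'
#' @param s_p,s_g D-score vectors.
#' @param label peak-group label vector.
#' @return combined D-score vector.
#' @export
combine_d_scores <- function(s_p, s_g, label) {
  is_target <- label == "target"
  X <- cbind(s_p = s_p, s_g = s_g)
  collinear <- FALSE
  fit <- withCallingHandlers(
    tryCatch(MASS::lda(X, grouping = factor(is_target)),
             error = function(e) NULL),
    warning = function(w) {
      if (grepl("collinear", conditionMessage(w))) collinear <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (collinear) fit <- NULL
  if (is.null(fit)) {
    warning("degenerate covariance in D-score combination; using equal weights")
    s <- (s_p + s_g) / sqrt(2)
  } else {
    s <- drop(X %*% fit$scaling[, 1])
  }
  if (mean(s[is_target]) < mean(s[!is_target])) s <- -s
  standardize_by(s, s[!is_target])
}

#' Flag the best peak group per queried precursor and run
#'
#' @param scored data.frame with `precursor_id`, `run_id`, `rt_apex`, `s_c`.
#' @return logical vector, `TRUE` for the peak group with the highest
#'   combined D-score (ties broken by earlier RT apex).
#' @export
flag_best_peak_groups <- function(scored) {
  key <- paste(scored$precursor_id, scored$run_id, sep = "\r")
  o <- order(key, -scored$s_c, scored$rt_apex)
  first <- !duplicated(key[o])
  out <- logical(nrow(scored))
  out[o] <- first
  out
}

storey_pi <- function(stat_pos, stat_null, lambda = 0.4) {
  v <- sort(stat_null)
  n <- length(v)
  p <- (1 + n - findInterval(stat_pos, v, left.open = TRUE)) / (n + 1)
  min(1, mean(p > lambda) / (1 - lambda))
}

#' Estimate the four mixture proportions
#'
#' Storey's method on empirical p-values against the decoy score
#' distributions: the peptide-null proportion from the peptide D-scores of
#' targets and glycan decoys versus peptide and both decoys; the
#' glycan-null proportion analogously; and the doubly-null proportion from
#' the combined D-scores of targets versus both decoys. The remaining
#' proportions follow by subtraction, clipped to `[0, 1]` and renormalized
#' to sum to one exactly.
#'
#' @param scored data.frame with `s_p`, `s_g`, `s_c`, `label`.
#' @param lambda Storey tuning parameter (default 0.4).
#' @return named list `pi00`, `pi01`, `pi10`, `pi11`.
#' @export
estimate_pi <- function(scored, lambda = 0.4) {
  lab <- scored$label
  for (cls in PEAKGROUP_LABELS)
    if (!any(lab == cls)) stop("no peak groups with label ", cls)
  pi_p <- storey_pi(scored$s_p[lab %in% c("target", "glycan_decoy")],
                    scored$s_p[lab %in% c("peptide_decoy", "both_decoy")], lambda)
  pi_g <- storey_pi(scored$s_g[lab %in% c("target", "peptide_decoy")],
                    scored$s_g[lab %in% c("glycan_decoy", "both_decoy")], lambda)
  pi00 <- storey_pi(scored$s_c[lab == "target"],
                    scored$s_c[lab == "both_decoy"], lambda)
  pi00 <- min(pi00, pi_p, pi_g)
  pis <- c(pi00 = pi00, pi01 = max(0, pi_p - pi00), pi10 = max(0, pi_g - pi00),
           pi11 = 0)
  pis["pi11"] <- max(0, 1 - sum(pis))
  pis <- pis / sum(pis)
  as.list(pis)
}

#' Fit the bivariate four-groups mixture model
#'
#' Bivariate Gaussian kernel density estimates of the four observed classes
#' (targets, glycan decoys, peptide decoys, both decoys) on a shared grid
#' spanning the observed D-scores plus a three-bandwidth margin, with a
#' normal-reference bandwidth per axis. The component densities for
#' "peptide null only" and "glycan null only" are recovered by
#' subtraction, clipped at zero and renormalized to unit mass.
#'
#' @param scored data.frame with `s_p`, `s_g`, `label`.
#' @param pis mixture proportions from [estimate_pi()].
#' @param grid_n grid resolution per axis (default 128).
#' @return an object of class `mixture_model_2d`.
#' @export
fit_mixture_2d <- function(scored, pis, grid_n = 128L) {
  bx <- stats::bw.nrd0(scored$s_p)
  by <- stats::bw.nrd0(scored$s_g)
  lims <- c(range(scored$s_p) + c(-3, 3) * bx, range(scored$s_g) + c(-3, 3) * by)
  kd <- function(sel) {
    MASS::kde2d(scored$s_p[sel], scored$s_g[sel], h = c(4 * bx, 4 * by),
                n = grid_n, lims = lims)
  }
  lab <- scored$label
  f_tt <- kd(lab == "target")
  f_td <- kd(lab == "glycan_decoy")
  f_dt <- kd(lab == "peptide_decoy")
  f_dd <- kd(lab == "both_decoy")
  cell <- diff(f_tt$x[1:2]) * diff(f_tt$y[1:2])
  renorm <- function(z) {
    z[z < 0] <- 0
    tot <- sum(z) * cell
    if (tot > 0) z / tot else z
  }
  f00 <- f_dd$z
  d01 <- pis$pi01 + pis$pi11
  d10 <- pis$pi10 + pis$pi11
  f01 <- if (d01 > 0) renorm((f_dt$z - (pis$pi00 + pis$pi10) * f00) / d01)
         else matrix(0, grid_n, grid_n)
  f10 <- if (d10 > 0) renorm((f_td$z - (pis$pi00 + pis$pi01) * f00) / d10)
         else matrix(0, grid_n, grid_n)
  structure(list(x = f_tt$x, y = f_tt$y, pis = pis, cell = cell,
                 f_tt = f_tt$z, f00 = f00, f01 = f01, f10 = f10),
            class = "mixture_model_2d")
}

#' @export
print.mixture_model_2d <- function(x, ...) {
  cat(sprintf("<mixture_model_2d> %dx%d grid; pi = (%.3f, %.3f, %.3f, %.3f)\n",
              length(x$x), length(x$y), x$pis$pi00, x$pis$pi01, x$pis$pi10,
              x$pis$pi11))
  invisible(x)
}

monotonize_grid <- function(z) {
  # non-increasing in both grid axes: cumulative minimum under product order
  m <- z
  for (i in seq_len(nrow(z))) {
    t <- if (i == 1L) m[i, ] else pmin(m[i, ], m[i - 1L, ])
    m[i, ] <- cummin(t)
  }
  m
}

bilinear_eval <- function(grid_x, grid_y, z, px, py) {
  px <- pmin(pmax(px, grid_x[1]), grid_x[length(grid_x)])
  py <- pmin(pmax(py, grid_y[1]), grid_y[length(grid_y)])
  ix <- pmin(pmax(findInterval(px, grid_x), 1L), length(grid_x) - 1L)
  iy <- pmin(pmax(findInterval(py, grid_y), 1L), length(grid_y) - 1L)
  fx <- (px - grid_x[ix]) / (grid_x[ix + 1L] - grid_x[ix])
  fy <- (py - grid_y[iy]) / (grid_y[iy + 1L] - grid_y[iy])
  n <- nrow(z)
  z11 <- z[cbind(ix, iy)]; z21 <- z[cbind(ix + 1L, iy)]
  z12 <- z[cbind(ix, iy + 1L)]; z22 <- z[cbind(ix + 1L, iy + 1L)]
  z11 * (1 - fx) * (1 - fy) + z21 * fx * (1 - fy) +
    z12 * (1 - fx) * fy + z22 * fx * fy
}

pep_grids <- function(model) {
  # eps regularizes empty-density regions: with all densities ~ 0 the
  # ratio tends to 1 (null), the conservative limit far from any data
  pis <- model$pis
  eps <- 1e-12 * max(model$f_tt)
  den <- model$f_tt + eps
  num_pg <- pis$pi00 * model$f00
  num_p <- num_pg + pis$pi01 * model$f01
  num_g <- num_pg + pis$pi10 * model$f10
  list(pep_p = (num_p + eps) / den, pep_g = (num_g + eps) / den,
       pep_pandg = (num_pg + eps) / den,
       pep_porg = (num_p + num_g - num_pg + eps) / den)
}

#' Posterior error probabilities from the fitted mixture
#'
#' Evaluates the peptide-null, glycan-null, both-null and either-null PEPs
#' at each (peptide, glycan) D-score pair by bilinear interpolation of the
#' mixture grids; scores outside the grid are evaluated at the nearest
#' boundary. Raw (unclipped, unmonotonized) components are returned in
#' `*_raw` columns; the reported components are clipped to `[0, 1]` and
#' monotonized so that PEP is non-increasing in both D-scores.
#'
#' @param s_p,s_g D-score vectors.
#' @param model fitted `mixture_model_2d`.
#' @param sparse_frac density floor, as a fraction of the peak target
#'   density: grid cells where the target density falls below it carry too
#'   few peak groups for a stable density ratio and are treated as null
#'   (PEP 1) before monotonization. Kernel tails in such cells would
#'   otherwise produce spuriously low PEPs that the monotone sweep
#'   propagates across the grid.
#' @return data.frame with columns `pep_p`, `pep_g`, `pep_pandg`,
#'   `pep_porg` and their `_raw` counterparts.
#' @export
compute_pep <- function(s_p, s_g, model, sparse_frac = 0.05) {
  g <- pep_grids(model)
  raw <- lapply(g, function(z) bilinear_eval(model$x, model$y, z, s_p, s_g))
  sparse <- model$f_tt < sparse_frac * max(model$f_tt)
  mono <- lapply(g, function(z) {
    z[sparse] <- 1
    v <- bilinear_eval(model$x, model$y, monotonize_grid(pmin(pmax(z, 0), 1)), s_p, s_g)
    pmin(pmax(v, 0), 1)  # guard against interpolation round-off
  })
  out <- data.frame(pep_p = mono$pep_p, pep_g = mono$pep_g,
                    pep_pandg = mono$pep_pandg, pep_porg = mono$pep_porg,
                    pep_p_raw = raw$pep_p, pep_g_raw = raw$pep_g,
                    pep_pandg_raw = raw$pep_pandg, pep_porg_raw = raw$pep_porg)
  out
}

#' q-values as average PEP over the acceptance set
#'
#' For each record, the q-value is the mean PEP over the smallest
#' acceptance set `{PEP <= t}` containing it.
#'
#' @param pep PEP vector in `[0, 1]`.
#' @return q-value vector.
#' @export
pep_to_qvalue <- function(pep) {
  stopifnot(all(pep >= 0 & pep <= 1, na.rm = TRUE))
  n <- length(pep)
  if (!n) return(numeric(0))
  o <- order(pep)
  cm <- cumsum(pep[o]) / seq_len(n)
  r <- rank(pep, ties.method = "max")
  cm[r]
}

#' Score candidate peak groups and estimate the 2D FDR
#'
#' Full run-level statistical workflow: learn peptide and glycan D-scores,
#' combine them, flag the best peak group per queried precursor and run,
#' estimate the mixture proportions and densities on the best peak groups,
#' compute PEPs for every peak group, and derive run-specific q-values at
#' peak-group level over the best target peak groups of each run.
#'
#' @param features peak-group feature data.frame.
#' @param seed integer seed.
#' @param lambda Storey tuning parameter.
#' @param grid_n mixture grid resolution.
#' @param ... passed to [learn_d_scores()].
#' @return list with `scores` (annotated data.frame), `model`
#'   (`mixture_model_2d`) and `pis`.
#' @export
score_peak_groups <- function(features, seed = 1L, lambda = 0.4,
                              grid_n = 128L, ...) {
  sc <- features
  sc$s_p <- learn_d_scores(features, "peptide", seed = seed, ...)
  sc$s_g <- learn_d_scores(features, "glycan", seed = seed + 1L, ...)
  sc$s_c <- combine_d_scores(sc$s_p, sc$s_g, sc$label)
  sc$is_best <- flag_best_peak_groups(sc)
  best <- sc[sc$is_best, , drop = FALSE]
  pis <- estimate_pi(best, lambda = lambda)
  model <- fit_mixture_2d(best, pis, grid_n = grid_n)
  sc <- cbind(sc, compute_pep(sc$s_p, sc$s_g, model))
  sc$q_run <- NA_real_
  tb <- sc$is_best & sc$label == "target"
  for (r in unique(sc$run_id[tb])) {
    sel <- tb & sc$run_id == r
    sc$q_run[sel] <- pep_to_qvalue(sc$pep_porg[sel])
  }
  list(scores = sc, model = model, pis = pis)
}

#' Global glycopeptide-level q-values and the default report filter
#'
#' Reduces the scored table to the best target peak group per glycopeptide
#' across all runs, recomputes q-values on that reduced set (the global
#' context), and flags glycopeptides passing the default report filter:
#' run q-value below `run_q` in every run where the glycopeptide was
#' queried, below `best_run_q` in at least one run, and global q-value
#' below `global_q`.
#'
#' @param scored scored data.frame from [score_peak_groups()].
#' @param run_q,best_run_q,global_q report thresholds (defaults 0.05, 0.01,
#'   0.01).
#' @return data.frame with one row per target glycopeptide: the best peak
#'   group's coordinates, `q_global` and `reported`.
#' @export
global_glycopeptide_qvalues <- function(scored, run_q = 0.05,
                                        best_run_q = 0.01, global_q = 0.01) {
  tb <- scored[scored$is_best & scored$label == "target", , drop = FALSE]
  if (!nrow(tb)) return(tb)
  o <- order(tb$glycopeptide_id, -tb$s_c, tb$rt_apex)
  best <- tb[o, , drop = FALSE]
  best <- best[!duplicated(best$glycopeptide_id), , drop = FALSE]
  best$q_global <- pep_to_qvalue(best$pep_porg)
  run_ok <- tapply(tb$q_run, tb$glycopeptide_id,
                   function(q) all(q < run_q) && any(q < best_run_q))
  best$reported <- unname(run_ok[best$glycopeptide_id]) & best$q_global < global_q
  rownames(best) <- NULL
  best
}
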