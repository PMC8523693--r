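test_that("D-score learning separates separable classes and is deterministic", {
  feat <- simulate_peak_group_features(n_targets = 600, pi = c(0, 0, 0, 1),
                                       separation = 20, seed = 1)
  s <- learn_d_scores(feat, "peptide", seed = 1)
  pl <- glycodia:::pseudo_labels(feat$label, "peptide")
  expect_equal(glycodia:::rank_auc(s[pl$pos | pl$neg], pl$pos[pl$pos | pl$neg]), 1)
  s2 <- learn_d_scores(feat, "peptide", seed = 1)
  expect_identical(s, s2)
})

test_that("D-scores on pure-noise sub-scores have chance-level AUC", {
  feat <- simulate_peak_group_features(n_targets = 2500, pi = c(1, 0, 0, 0),
                                       separation = 0, seed = 2)
  s <- learn_d_scores(feat, "glycan", seed = 2)
  pl <- glycodia:::pseudo_labels(feat$label, "glycan")
  auc <- glycodia:::rank_auc(s[pl$pos | pl$neg], pl$pos[pl$pos | pl$neg])
  expect_lt(abs(auc - 0.5), 0.03)
})

test_that("learning refuses to run with too few training peak groups", {
  feat <- simulate_peak_group_features(n_targets = 50, seed = 3)
  expect_error(learn_d_scores(feat, "peptide", seed = 1), "larger spectral library")
})

test_that("combined D-scores preserve rank and flag best peak groups", {
  feat <- simulate_peak_group_features(n_targets = 400, seed = 4)
  s <- rnorm(nrow(feat)) + 2 * (feat$label == "target")
  sc <- suppressWarnings(combine_d_scores(s, s, feat$label))
  expect_equal(order(sc), order(s))
  df <- data.frame(precursor_id = c("a", "a", "b"), run_id = "r",
                   rt_apex = c(10, 5, 7), s_c = c(3.1, 2.9, 1))
  expect_equal(flag_best_peak_groups(df), c(TRUE, FALSE, TRUE))
  # tie on s_c: earlier RT apex wins
  df2 <- data.frame(precursor_id = "a", run_id = "r",
                    rt_apex = c(10, 5), s_c = c(2, 2))
  expect_equal(flag_best_peak_groups(df2), c(FALSE, TRUE))
})

test_that("mixture proportions recover degenerate truths and sum to one", {
  # all targets null on both axes: pi00 -> 1
  f0 <- simulate_peak_group_features(n_targets = 10000, pi = c(1, 0, 0, 0),
                                     separation = 3, seed = 5)
  sc0 <- score_peak_groups(f0, seed = 5)
  expect_gt(sc0$pis$pi00, 0.95)
  # all targets fully separated from all decoys: pi11 -> 1
  f1 <- simulate_peak_group_features(n_targets = 10000, pi = c(0, 0, 0, 1),
                                     separation = 4, seed = 6)
  sc1 <- score_peak_groups(f1, seed = 6)
  expect_gt(sc1$pis$pi11, 0.95)
  expect_equal(sc0$pis$pi00 + sc0$pis$pi01 + sc0$pis$pi10 + sc0$pis$pi11, 1)
  expect_equal(sc1$pis$pi00 + sc1$pis$pi01 + sc1$pis$pi10 + sc1$pis$pi11, 1)
  feat <- simulate_peak_group_features(n_targets = 300, seed = 7)
  feat <- feat[feat$label != "both_decoy", ]
  expect_error(estimate_pi(transform(feat, s_p = 0, s_g = 0, s_c = 0)),
               "both_decoy")
})

test_that("the union PEP identity holds to 1e-10 before monotonization", {
  feat <- simulate_peak_group_features(n_targets = 3000, seed = 8)
  res <- score_peak_groups(feat, seed = 8)
  sc <- res$scores
  expect_lt(max(abs(sc$pep_porg_raw -
                      (sc$pep_p_raw + sc$pep_g_raw - sc$pep_pandg_raw))), 1e-10)
  # reported PEPs are probabilities; intersection never exceeds components
  for (col in c("pep_p", "pep_g", "pep_pandg", "pep_porg"))
    expect_true(all(sc[[col]] >= 0 & sc[[col]] <= 1))
  # degenerate all-null model: union PEP is 1 everywhere
  model0 <- res$model
  model0$pis <- list(pi00 = 1, pi01 = 0, pi10 = 0, pi11 = 0)
  model0$f_tt <- model0$f00
  pep0 <- compute_pep(sc$s_p, sc$s_g, model0)
  expect_true(all(abs(pep0$pep_porg_raw - 1) < 1e-6))
})

test_that("monotonized PEP is non-increasing in both D-scores", {
  feat <- simulate_peak_group_features(n_targets = 3000, seed = 9)
  res <- score_peak_groups(feat, seed = 9)
  grid <- seq(-3, 6, length.out = 40)
  for (fixed in c(-1, 1, 3)) {
    along_p <- compute_pep(grid, rep(fixed, 40), res$model)$pep_porg
    along_g <- compute_pep(rep(fixed, 40), grid, res$model)$pep_porg
    expect_true(all(diff(along_p) <= 1e-9))
    expect_true(all(diff(along_g) <= 1e-9))
  }
  # brute-force oracle: the monotonized grid equals the cumulative minimum
  g <- glycodia:::pep_grids(res$model)$pep_porg
  g <- pmin(pmax(g, 0), 1)
  m <- glycodia:::monotonize_grid(g)
  n <- nrow(g)
  brute <- g
  for (i in seq_len(n)) for (j in seq_len(n))
    brute[i, j] <- min(g[seq_len(i), seq_len(j)])
  expect_equal(m, brute)
})

test_that("q-values are averages of PEPs over acceptance sets", {
  expect_equal(pep_to_qvalue(c(0.01, 0.02, 0.03)), c(0.01, 0.015, 0.02))
  expect_equal(pep_to_qvalue(c(0.03, 0.01, 0.02)), c(0.02, 0.01, 0.015))
  expect_equal(pep_to_qvalue(rep(0.2, 5)), rep(0.2, 5))
  # non-decreasing with increasing PEP threshold
  set.seed(10)
  pep <- runif(200)
  q <- pep_to_qvalue(pep)
  expect_true(all(diff(q[order(pep)]) >= -1e-12))
  expect_true(all(q <= pep | abs(q - pep) < 1e-12))
})

test_that("target-decoy q-values count decoys above each score", {
  q <- td_qvalues(c(5, 4, 3, 2, 1), c(2.5, 1.5))
  expect_equal(q, c(0, 0, 0, 1 / 4, 2 / 5))
})

test_that("the global context keeps one representative per glycopeptide", {
  feat <- simulate_peak_group_features(n_targets = 1000, seed = 11)
  # replicate the same glycopeptides over 3 runs
  reps <- do.call(rbind, lapply(1:3, function(r) {
    f <- feat
    f$run_id <- paste0("run", r)
    f$peak_group_id <- paste0(f$peak_group_id, "_", r)
    f
  }))
  res <- score_peak_groups(reps, seed = 11)
  glob <- global_glycopeptide_qvalues(res$scores)
  tgt <- res$scores[res$scores$label == "target", ]
  expect_equal(nrow(glob), length(unique(tgt$glycopeptide_id)))
  expect_false(any(duplicated(glob$glycopeptide_id)))
  # single run: global set equals the per-run best set
  res1 <- score_peak_groups(feat, seed = 11)
  glob1 <- global_glycopeptide_qvalues(res1$scores)
  expect_setequal(glob1$peak_group_id,
                  res1$scores$peak_group_id[res1$scores$is_best &
                                              res1$scores$label == "target"])
  expect_type(glob$reported, "logical")
})
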