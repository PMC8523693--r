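test_that("glycoform priors divide 1 - PEP_MS2 over compositions", {
  hyps <- lapply(c("A", "B", "C", "D"), make_hyp)
  post <- bhm_posterior(hyps, pep_ms2 = 0.2)
  expect_equal(post$prior, rep(0.2, 5))
  # isomer groups split their composition's prior equally
  hyps2 <- lapply(c("A", "A", "B"), make_hyp)
  post2 <- bhm_posterior(hyps2, pep_ms2 = 0.2)
  expect_equal(post2$prior, c(0.2, 0.2, 0.2, 0.4))
  expect_equal(sum(post2$prior), 1)
})

test_that("uninformative evidence leaves the posterior at the prior", {
  hyps <- lapply(c("A", "B", "C"), make_hyp, fragment_keys = c("N1", "N2"))
  trans <- data.frame(transition_id = c("t1", "t2"), pep = c(0.5, 0.5))
  trans$hypotheses <- list(1:3, 1:3)
  post <- bhm_posterior(hyps, pep_ms2 = 0.4, pep_ms1 = 0.5,
                        in_tolerance = rep(TRUE, 3),
                        transitions = trans)
  expect_equal(post$p_g, post$prior, tolerance = 1e-12)
  expect_equal(post$p_g_t, post$prior, tolerance = 1e-12)
})

test_that("hierarchical posteriors match a hand-computed Bayes table", {
  # 2 hypotheses + incorrect detection, one discriminating transition
  hyps <- list(make_hyp("H5N2", is_target = TRUE), make_hyp("H4N2"))
  trans <- data.frame(transition_id = "t1", pep = 0.1)
  trans$hypotheses <- list(1L)
  post <- bhm_posterior(hyps, pep_ms2 = 0.2, transitions = trans)
  prior <- c(0.2, 0.4, 0.4)
  lik <- c(0.1, 0.9, 0.1)  # member -> 1 - pep, else pep
  expect_equal(post$p_g_t, prior * lik / sum(prior * lik), tolerance = 1e-12)
})

test_that("posteriors equal brute-force enumeration on all small cases", {
  set.seed(17)
  for (case in 1:25) {
    nh <- sample(1:4, 1)
    nt <- sample(0:6, 1)
    comps <- sample(c("H5N2", "H4N2", "F1H4N2", "H6N2"), nh, replace = TRUE)
    hyps <- lapply(seq_len(nh), function(i)
      make_hyp(comps[i], precursor_mz = 1000 + i * runif(1, 0, 0.02),
               is_target = i == 1))
    pep_ms2 <- runif(1, 0.01, 0.99)
    pep_ms1 <- runif(1, 0.01, 0.99)
    in_tol <- runif(nh) < 0.6
    prec_pep <- runif(nh, 0.01, 0.99)
    trans <- NULL
    if (nt > 0) {
      trans <- data.frame(transition_id = paste0("t", seq_len(nt)),
                          pep = runif(nt, 0.01, 0.99))
      trans$hypotheses <- lapply(seq_len(nt), function(j)
        which(runif(nh) < 0.5))
    }
    got <- bhm_posterior(hyps, pep_ms2, pep_ms1, in_tol, prec_pep, trans)
    want <- oracle_bhm(hyps, pep_ms2, pep_ms1, in_tol, prec_pep, trans)
    expect_equal(got$prior, want$prior, tolerance = 1e-12)
    expect_equal(got$p_g, want$p_g, tolerance = 1e-12)
    expect_equal(got$p_g_t, want$p_g_t, tolerance = 1e-12)
    expect_lt(abs(sum(got$p_g) - 1), 1e-10)
    expect_lt(abs(sum(got$p_g_t) - 1), 1e-10)
    expect_lt(abs(sum(got$prior) - 1), 1e-10)
  }
})

test_that("stronger private evidence never lowers the supported posterior", {
  hyps <- list(make_hyp("H5N2", is_target = TRUE), make_hyp("F1H4N2"))
  pp <- vapply(seq(0.9, 0.05, by = -0.05), function(pep_private) {
    trans <- data.frame(transition_id = c("shared", "private"),
                        pep = c(0.3, pep_private))
    trans$hypotheses <- list(1:2, 1L)
    post <- bhm_posterior(hyps, pep_ms2 = 0.1, transitions = trans)
    post$p_g_t[post$hypothesis == 1]
  }, 0)
  expect_true(all(diff(pp) >= -1e-12))
})

test_that("composition PPs sum isomer posteriors and conserve mass", {
  hyps <- list(make_hyp("H5N2", structures = "s1", is_target = TRUE),
               make_hyp("H5N2", structures = "s2", is_target = TRUE),
               make_hyp("H4N2", structures = "s3"))
  trans <- data.frame(transition_id = "t", pep = 0.2)
  trans$hypotheses <- list(c(1L, 2L))
  post <- bhm_posterior(hyps, pep_ms2 = 0.3, transitions = trans)
  agg <- aggregate_composition_pp(post)
  expect_equal(agg$pp[!is.na(agg$composition) & agg$composition == "H5N2"],
               sum(post$p_g_t[post$hypothesis %in% 1:2]))
  expect_equal(sum(agg$pp), 1, tolerance = 1e-10)
  # single-structure composition: PP equals the structure posterior
  expect_equal(agg$pp[!is.na(agg$composition) & agg$composition == "H4N2"],
               post$p_g_t[post$hypothesis == 3])
})

test_that("background glycoform selection ranks by Jaccard within the window", {
  target <- "(N(N(H(H)(H))))"
  peptide <- "LVDJGTSAK"
  z <- 2L
  # candidates: one near-identical glycan and one distant, same window
  near <- "(N(N(H(H)(H(H)))))"
  db <- c(target, near)
  hyps <- select_background_glycoforms(peptide, "", target, z, db,
                                       scheme = isolation_scheme(seq(500, 2000, 25), 1000))
  expect_true(hyps[[1]]$is_target)
  # n_bg = 0 keeps only the target
  h0 <- select_background_glycoforms(peptide, "", target, z, db, n_bg = 0,
                                     scheme = isolation_scheme(seq(500, 2000, 25), 1000))
  expect_length(h0, 1L)
  # db containing only the target: one glycoform hypothesis
  h1 <- select_background_glycoforms(peptide, "", target, z, target)
  expect_length(h1, 1L)
  # ranking: the higher-Jaccard candidate is kept at n_bg = 1
  far <- "(N(N(H(H(A)(A))(H(A)))(F)))"
  wide <- isolation_scheme(1250, 4000)  # everything co-isolated
  h2 <- select_background_glycoforms(peptide, "", target, z, c(near, far),
                                     scheme = wide, n_bg = 1)
  expect_length(h2, 2L)
  expect_equal(h2[[2]]$structures, serialize_glycan(parse_glycan(near)))
  # empty db
  h3 <- select_background_glycoforms(peptide, "", target, z, character(0))
  expect_length(h3, 1L)
})

test_that("identification transitions map to their originating hypotheses", {
  # toy pair: chain N-N-H vs chain N-N-F
  hyps <- list(
    make_hyp("H1N2", fragment_keys = enumerate_y_fragments("(N(N(H)))")$keys,
             precursor_mz = 1000, is_target = TRUE),
    make_hyp("F1N2", fragment_keys = enumerate_y_fragments("(N(N(F)))")$keys,
             precursor_mz = 995))
  tr <- generate_identification_transitions(hyps, "LVDJGTSAK", "",
                                            charges = 1L, scan_range = c(1, 1e5))
  y <- tr[tr$type == "y_ion", ]
  shared <- y$composition %in% c("0", "N1", "N2")
  expect_true(all(vapply(y$hypotheses[shared], identical, TRUE, c(1L, 2L))))
  # discriminating transitions are exactly the symmetric difference
  expect_equal(y$hypotheses[y$composition == "H1N2"], list(1L))
  expect_equal(y$hypotheses[y$composition == "F1N2"], list(2L))
  # one precursor transition per hypothesis
  expect_equal(sum(tr$type == "precursor"), 2L)
  # single hypothesis: every transition maps to it
  tr1 <- generate_identification_transitions(hyps[1], "LVDJGTSAK", "",
                                             charges = 1L, scan_range = c(1, 1e5))
  expect_true(all(vapply(tr1$hypotheses, identical, TRUE, 1L)))
})

test_that("transition PEPs separate signal from decoy-like transitions", {
  set.seed(23)
  decoys <- rnorm(5000)
  null_like <- rnorm(2500)
  signal <- rnorm(2500, 4)
  peps <- transition_peps(c(null_like, signal), decoys)
  expect_gte(mean(peps[seq_len(2500)] > 0.9), 0.5)
  expect_lt(stats::median(peps[2501:5000]), 0.1)
  expect_true(all(peps >= 0 & peps <= 1))
  expect_error(transition_peps(signal, numeric(0)), "decoy")
})

test_that("multi-score transition features reduce to calibrated PEPs", {
  set.seed(29)
  n <- 2000
  feats <- data.frame(co = c(rnorm(n, 3), rnorm(n)), shape = rnorm(2 * n))
  decoys <- data.frame(co = rnorm(2 * n), shape = rnorm(2 * n))
  out <- score_identification_transitions(feats, decoys)
  expect_length(out$pep, 2 * n)
  expect_lt(median(out$pep[seq_len(n)]), 0.1)       # signal transitions
  expect_gt(median(out$pep[n + seq_len(n)]), 0.5)   # decoy-like transitions
  expect_error(score_identification_transitions(feats, decoys[0, ]), "decoy")
})

test_that("glycoform q-values average the PEPs of accepted peak groups", {
  out <- glycoform_qvalues(c(0.99, 0.98))
  expect_equal(out$pep, c(0.01, 0.02))
  expect_equal(out$q, c(0.01, 0.015))
  expect_equal(glycoform_qvalues(1)$pep, 0)
  expect_equal(glycoform_qvalues(1)$q, 0)
})
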