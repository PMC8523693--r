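test_that("RT prediction evaluates the Gaussian-weighted mean exactly", {
  nb <- function(d, rt) {
    structure(list(ok = TRUE, s_p_rt = data.frame(NormalizedRetentionTime = rt),
                   d_rt = d), class = "neighbor_set")
  }
  expect_equal(predict_rt(nb(c(1, 1, 1), c(30, 30, 30))), 30)
  expect_equal(predict_rt(nb(c(2, 2, 2), c(10, 20, 30))), 20)
  # direct evaluation oracle: w_i prop exp(-d_i^2 / (2 sigma^2)), sigma^2 = mean(d^2)
  d <- c(1, 2); rt <- c(10, 40)
  s2 <- mean(d^2)
  w <- exp(-d^2 / (2 * s2))
  expect_equal(predict_rt(nb(d, rt)), sum(w * rt) / sum(w), tolerance = 1e-12)
  expect_equal(predict_rt(nb(d, rt)), 20.6303, tolerance = 0.01)
  # all-zero distances: uniform weights, no division by zero
  expect_equal(predict_rt(nb(c(0, 0), c(10, 20))), 15)
})

test_that("RT weights are invariant to uniform distance scaling", {
  d <- c(0.5, 1.7, 2.2)
  w1 <- knn_rt_weights(d); w2 <- knn_rt_weights(10 * d)
  expect_equal(w1 / sum(w1), w2 / sum(w2), tolerance = 1e-12)
})

test_that("neighbor search respects k, ties and the insufficiency rule", {
  lib <- toy_library(n_peptides = 5, n_glycans = 5)
  p <- lib$precursors[1, ]
  nb <- find_neighbors(p$Peptide, p$GlycanStructure, p$Charge, lib, k = 3,
                       exclude_id = p$PrecursorId)
  expect_true(nb$ok)
  expect_equal(nrow(nb$s_pk), 3L)
  expect_equal(nrow(nb$s_gk), 3L)
  expect_false(p$PrecursorId %in% c(nb$s_pk$PrecursorId, nb$s_gk$PrecursorId))
  # distances are the k smallest available
  all_sp <- lib$precursors[lib$precursors$Peptide == p$Peptide &
                             lib$precursors$Charge == p$Charge &
                             lib$precursors$PrecursorId != p$PrecursorId, ]
  d_all <- sort(vapply(all_sp$GlycanComposition, function(x)
    sqrt(sum((glycan_vector(x) - glycan_vector(p$GlycanComposition))^2)), 0))
  expect_equal(sort(nb$d_pk), unname(d_all[1:3]), tolerance = 1e-12)
  # k larger than the neighborhood: skip with a reason
  nb_big <- find_neighbors(p$Peptide, p$GlycanStructure, p$Charge, lib, k = 50,
                           exclude_id = p$PrecursorId)
  expect_false(nb_big$ok)
  expect_match(nb_big$reason, "insufficient neighbors")
})

test_that("an exact duplicate neighbor is recovered with DP 1 and zero RT error", {
  lib <- toy_library(n_peptides = 4, n_glycans = 4)
  # duplicate the first precursor under a synthetic modified id
  dup_p <- lib$precursors[1, ]
  dup_p$PrecursorId <- paste0(dup_p$PrecursorId, "_dup")
  dup_t <- lib$transitions[lib$transitions$PrecursorId ==
                             lib$precursors$PrecursorId[1], ]
  dup_t$PrecursorId <- dup_p$PrecursorId
  lib2 <- glyco_library(rbind(lib$precursors, dup_p),
                        rbind(lib$transitions, dup_t))
  cv <- cross_validate(lib2, k = 1)
  res <- cv$results
  orig <- res[res$precursor_id == lib$precursors$PrecursorId[1], ]
  expect_equal(orig$dp, 1, tolerance = 1e-9)
  expect_equal(orig$rt_error, 0, tolerance = 1e-9)
})

test_that("cross-validation recovers spectra on a separable simulated library", {
  # composition-unique glycans: swap partners then share the exact fragment
  # patterns, the separability assumption the predictor relies on
  db <- simulate_glycan_db(20, seed = 42, codes = c("H", "N"), max_extra = 3)
  comps <- vapply(db, function(s) composition_key(glycan_composition(s)), "")
  db <- head(db[!duplicated(comps)], 6)
  lib <- simulate_library(n_peptides = 8, glycan_db = db,
                          glycans_per_peptide = 6, replicates = 1,
                          seed = 42, charge = 3, rep_noise_sd = 0.05)$library
  cv <- cross_validate(lib, k = 3)
  expect_gt(cv$summary$n_predicted, 10)
  expect_gte(cv$summary$median_dp, 0.95)
  expect_lt(cv$summary$rt_iqr, 1)
  expect_gt(cv$summary$rt_pearson_r, 0.99)
  # k beyond every neighborhood: nothing predictable
  cv_none <- cross_validate(lib, k = 100)
  expect_equal(cv_none$summary$n_predicted, 0L)
})

test_that("library extension adds only listed, novel, predictable combinations", {
  # each peptide carries 5 of 6 glycans, so novel combinations exist while
  # every (peptide, glycan) neighborhood still holds >= 3 entries
  db <- simulate_glycan_db(6, seed = 42, codes = c("H", "N"))
  lib <- simulate_library(n_peptides = 6, glycan_db = db,
                          glycans_per_peptide = 5, replicates = 1,
                          seed = 42, charge = 3)$library
  expect_identical(extend_library(lib, data.frame()), lib)
  # list containing only combinations already in the base: identity
  have <- unique(lib$precursors[c("Peptide", "Modifications", "GlycanComposition")])
  expect_equal(nrow(extend_library(lib, have)$precursors),
               nrow(lib$precursors))
  # one novel combination: a (peptide, glycan) pair absent from the library
  combos <- expand.grid(Peptide = unique(lib$precursors$Peptide),
                        GlycanComposition = unique(lib$precursors$GlycanComposition),
                        stringsAsFactors = FALSE)
  combos$Modifications <- ""
  key_have <- paste(have$Peptide, have$GlycanComposition)
  novel <- combos[!paste(combos$Peptide, combos$GlycanComposition) %in% key_have, ]
  expect_gt(nrow(novel), 0)
  ext <- extend_library(lib, novel[1, ], k = 3)
  expect_equal(nrow(ext$precursors), nrow(lib$precursors) + 1L)
  added <- ext$precursors[!ext$precursors$PrecursorId %in%
                            lib$precursors$PrecursorId, ]
  expect_equal(added$Provenance, "semi-empirical")
  # predicted entries satisfy the library transition invariants
  tr <- ext$transitions[ext$transitions$PrecursorId == added$PrecursorId, ]
  expect_gte(sum(tr$Part == "peptide"), 3L)
  expect_gte(sum(tr$Part == "glycan"), 3L)
  expect_lte(sum(tr$Part == "peptide"), 10L)
  expect_lte(sum(tr$Part == "glycan"), 10L)
})
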