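mk_gpsm <- function(peptide = "AJK", glycan = "(N(N(H(H)(H))))", charge = 2,
                    score = 10, rt = 30, spectrum = NULL, run = "r1") {
  list(peptide = peptide, mods = NULL, glycan = glycan, charge = charge,
       total_score = score, rt = rt, run_id = run, spectrum = spectrum)
}

# a spectrum holding every theoretical fragment of the precursor
full_spectrum <- function(peptide, glycan, intensities = NULL) {
  theo <- theoretical_transitions(peptide, NULL, glycan)
  o <- order(theo$ProductMz)
  if (is.null(intensities)) intensities <- rep(100, nrow(theo))
  data.frame(mz = theo$ProductMz[o], intensity = intensities[o])
}

test_that("theoretical fragment masses match residue-mass arithmetic", {
  # y1 of AJK is the K immonium-free y ion: K + water + proton
  expect_equal(backbone_fragment_mz("AJK", "y", 1, 1),
               128.09496 + 18.0105646863 + 1.00727646, tolerance = 1e-6)
  expect_equal(round(backbone_fragment_mz("AJK", "y", 1, 1), 4), 147.1128)
  # Y0 at 2+ is (peptide mass + 2 protons) / 2
  pm <- peptide_mass("AJK")
  expect_equal(y_ion_mz(pm, 0, 2), (pm + 2 * 1.00727646) / 2)
  # modifications shift only fragments containing the modified residue
  mods <- data.frame(position = 3, delta = 57.02146)
  expect_equal(backbone_fragment_mz("AJK", "b", 2, 1, mods),
               backbone_fragment_mz("AJK", "b", 2, 1))
  expect_equal(backbone_fragment_mz("AJK", "y", 1, 1, mods),
               backbone_fragment_mz("AJK", "y", 1, 1) + 57.02146)
})

test_that("spectrum annotation claims nearest peaks within 20 ppm only", {
  sp <- full_spectrum("AJK", "(N(N(H)))")
  g <- mk_gpsm(glycan = "(N(N(H)))", spectrum = sp)
  ann <- annotate_spectrum(g)
  expect_gt(nrow(ann), 10)
  expect_true(all(ann$LibraryIntensity == 100))
  # shift one theoretical peak by 25 ppm: it must lose its annotation
  y1 <- backbone_fragment_mz("AJK", "y", 1, 1)
  sp2 <- sp[abs(sp$mz - y1) > 1e-9, , drop = FALSE]
  sp2 <- rbind(sp2, data.frame(mz = y1 * (1 + 25e-6), intensity = 100))
  sp2 <- sp2[order(sp2$mz), ]
  ann2 <- annotate_spectrum(mk_gpsm(glycan = "(N(N(H)))", spectrum = sp2))
  expect_false(any(ann2$FragmentType == "y" & ann2$FragmentSeriesNumber == 1 &
                     ann2$FragmentCharge == 1))
  # but within 20 ppm it is annotated
  sp3 <- rbind(sp2[abs(sp2$mz - y1 * (1 + 25e-6)) > 1e-9, ],
               data.frame(mz = y1 * (1 + 15e-6), intensity = 100))
  sp3 <- sp3[order(sp3$mz), ]
  ann3 <- annotate_spectrum(mk_gpsm(glycan = "(N(N(H)))", spectrum = sp3))
  expect_true(any(ann3$FragmentType == "y" & ann3$FragmentSeriesNumber == 1 &
                    ann3$FragmentCharge == 1))
})

test_that("best-structure selection sums scores and breaks ties canonically", {
  s1 <- "(N(H(H)))"; s2 <- "(N(H)(H))"  # isomers, same composition
  gp <- list(mk_gpsm(glycan = s1, score = 10), mk_gpsm(glycan = s1, score = 5),
             mk_gpsm(glycan = s2, score = 14))
  kept <- select_best_structure(gp)
  expect_length(kept, 2L)
  expect_true(all(vapply(kept, function(g) g$glycan, "") == s1))
  # single structure: all kept
  expect_length(select_best_structure(gp[1:2]), 2L)
  # exact tie: canonical string order decides, stable under permutation
  tie <- list(mk_gpsm(glycan = s1, score = 7), mk_gpsm(glycan = s2, score = 7))
  w1 <- select_best_structure(tie)[[1]]$glycan
  w2 <- select_best_structure(rev(tie))[[1]]$glycan
  expect_equal(w1, w2)
  expect_equal(w1, sort(c(s1, s2))[1])
  expect_error(select_best_structure(list()), "no GPSMs")
})

test_that("consensus keeps peaks present in strictly more than 60% of replicates", {
  theo <- theoretical_transitions("AJK", NULL, "(N(N(H)))")
  theo$LibraryIntensity <- 100
  drop_first <- function(tr) tr[-1, , drop = FALSE]
  # 5 replicates; the first transition present in only 3 (60%) -> dropped
  reps3of5 <- c(replicate(3, theo, simplify = FALSE),
                replicate(2, drop_first(theo), simplify = FALSE))
  out <- build_consensus(reps3of5, scores = rep(1, 5))
  expect_false(transition_key(theo)[1] %in% transition_key(out$transitions))
  # present in 4 of 5 (> 60%) -> kept
  reps4of5 <- c(replicate(4, theo, simplify = FALSE),
                list(drop_first(theo)))
  out4 <- build_consensus(reps4of5, scores = rep(1, 5))
  expect_true(transition_key(theo)[1] %in% transition_key(out4$transitions))
  # one replicate is returned unchanged
  out1 <- build_consensus(list(theo), scores = 2)
  expect_setequal(transition_key(out1$transitions), transition_key(theo))
  # identical replicates with different scores: weighted mean of equal values
  out2 <- build_consensus(list(theo, theo), scores = c(1, 3))
  expect_true(all(out2$transitions$LibraryIntensity == 100))
})

test_that("consensus is permutation-invariant and drops dissimilar replicates", {
  theo <- theoretical_transitions("AJK", NULL, "(N(N(H)))")
  set.seed(3)
  reps <- lapply(1:4, function(i) {
    tr <- theo
    tr$LibraryIntensity <- exp(rnorm(nrow(tr), 4, 0.1)) + i
    tr
  })
  scores <- c(5, 7, 2, 9)
  a <- build_consensus(reps, scores)$transitions
  perm <- c(3, 1, 4, 2)
  b <- build_consensus(reps[perm], scores[perm])$transitions
  expect_equal(a, b)
  # an anti-correlated replicate is discarded
  odd <- theo
  odd$LibraryIntensity <- rev(seq_len(nrow(odd)))^4
  base <- theo; base$LibraryIntensity <- seq_len(nrow(theo))^4
  out <- build_consensus(list(base, base, odd), scores = c(1, 1, 100))
  expect_equal(out$used, c(TRUE, TRUE, FALSE))
})

test_that("transition filters enforce the 10+10 / 6+6 / 3+3 rules", {
  mk_tr <- function(part, n, mz0) data.frame(
    FragmentType = if (part == "glycan") "Y" else "y",
    FragmentSeriesNumber = if (part == "glycan") NA_integer_ else seq_len(n),
    FragmentComposition = if (part == "glycan") paste0("H", seq_len(n)) else NA,
    FragmentCharge = 1L, ProductMz = mz0 + seq_len(n) * 10,
    LibraryIntensity = 100 + seq_len(n), Part = part,
    stringsAsFactors = FALSE)
  tr <- rbind(mk_tr("peptide", 15, 200), mk_tr("glycan", 12, 400))
  out <- filter_transitions(tr, precursor_mz = 1000)
  expect_equal(sum(out$Part == "peptide"), 10L)
  expect_equal(sum(out$Part == "glycan"), 10L)
  expect_equal(sum(out$IsQuantifier & out$Part == "peptide"), 6L)
  expect_equal(sum(out$IsQuantifier & out$Part == "glycan"), 6L)
  # the kept transitions are the most intense ones
  expect_true(all(out$LibraryIntensity[out$Part == "peptide"] >=
                    sort(tr$LibraryIntensity[tr$Part == "peptide"], TRUE)[10]))
  # fewer than 3 glycan transitions after exclusion -> entry dropped
  tr2 <- rbind(mk_tr("peptide", 5, 200), mk_tr("glycan", 2, 400))
  expect_null(filter_transitions(tr2, precursor_mz = 1000))
  # fragment inside the precursor's own isolation window is excluded
  tr3 <- rbind(mk_tr("peptide", 5, 200), mk_tr("glycan", 5, 400))
  tr3 <- rbind(tr3, data.frame(FragmentType = "Y", FragmentSeriesNumber = NA,
                               FragmentComposition = "H9", FragmentCharge = 1L,
                               ProductMz = 1001, LibraryIntensity = 1e6,
                               Part = "glycan", stringsAsFactors = FALSE))
  out3 <- filter_transitions(tr3, precursor_mz = 1000)
  expect_false(1001 %in% out3$ProductMz)
  # out-of-scan-range fragments are excluded
  tr4 <- tr3
  tr4$ProductMz[1] <- 150
  out4 <- filter_transitions(tr4, precursor_mz = 1000)
  expect_false(150 %in% out4$ProductMz)
})

test_that("RT calibration recovers affine anchor maps", {
  anchors <- data.frame(rt_source = seq(5, 55, length.out = 30),
                        rt_target = seq(5, 55, length.out = 30))
  rts <- c(10, 25.3, 40)
  expect_equal(calibrate_rt(anchors, rts), rts, tolerance = 1e-6)
  anchors2 <- data.frame(rt_source = seq(5, 55, length.out = 30),
                         rt_target = 2 * seq(5, 55, length.out = 30))
  out <- calibrate_rt(anchors2, rts)
  expect_equal(out, 2 * rts, tolerance = 0.01 * max(2 * rts))
  expect_error(calibrate_rt(anchors[1:3, ], rts), "at least 10")
})

test_that("library merging unions entries and resolves duplicates", {
  lib <- toy_library()
  n <- nrow(lib$precursors)
  half1 <- glyco_library(lib$precursors[1:3, ],
                         lib$transitions[lib$transitions$PrecursorId %in%
                                           lib$precursors$PrecursorId[1:3], ])
  half2 <- glyco_library(lib$precursors[4:n, ],
                         lib$transitions[lib$transitions$PrecursorId %in%
                                           lib$precursors$PrecursorId[4:n], ])
  merged <- merge_libraries(half1, half2)
  expect_setequal(merged$precursors$PrecursorId, lib$precursors$PrecursorId)
  # duplicate precursor: higher replicate count wins
  dup <- half1
  dup$precursors$ReplicateCount <- dup$precursors$ReplicateCount + 5L
  dup$precursors$SumScore <- -1
  merged2 <- merge_libraries(half1, dup)
  expect_equal(nrow(merged2$precursors), 3L)
  expect_true(all(merged2$precursors$SumScore == -1))
  # merging with an empty library is the identity
  merged3 <- merge_libraries(lib, empty_library())
  expect_equal(nrow(merged3$precursors), n)
})

test_that("library-level RT calibration maps entries and exports anchors", {
  lib <- toy_library(n_peptides = 3, n_glycans = 3)
  anchors <- data.frame(rt_source = seq(0, 60, length.out = 20),
                        rt_target = 2 * seq(0, 60, length.out = 20),
                        PrecursorId = rep(lib$precursors$PrecursorId[1:2], 10))
  path <- withr::local_tempfile(fileext = ".traML")
  out <- calibrate_library_rt(lib, anchors, traml_path = path)
  expect_equal(out$precursors$NormalizedRetentionTime,
               2 * lib$precursors$NormalizedRetentionTime, tolerance = 0.02)
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "t")
  expect_length(xml2::xml_find_all(doc, "//t:Peptide", ns), 2L)
})

test_that("library building from simulated GPSMs satisfies the entry invariants", {
  lib <- toy_library()
  expect_gt(nrow(lib$precursors), 0)
  cnt <- table(lib$transitions$PrecursorId, lib$transitions$Part)
  expect_true(all(cnt >= 3L))
  expect_true(all(cnt <= 10L))
  qcnt <- tapply(lib$transitions$IsQuantifier,
                 paste(lib$transitions$PrecursorId, lib$transitions$Part), sum)
  expect_true(all(qcnt <= 6L))
})
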