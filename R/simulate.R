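#' Synthetic data generation
#'
#' Desk-scale stand-ins for the inputs the statistical machinery consumes:
#' glycan structure databases grown from the N-glycan core, glycopeptide
#' libraries with separable peptide/glycan fragment-intensity structure,
#' four-class peak-group feature tables matching the mixture model's
#' generative assumptions, transition-level glycoform signals, and
#' entrapment benchmarks. All generators are fully deterministic under
#' their seed.
#'
#' @name simulate
NULL

N_GLYCAN_CORE <- "(N(N(H(H)(H))))"

flatten_glycan <- function(g) {
  code <- character(0); parent <- integer(0)
  walk <- function(node, par) {
    code[length(code) + 1L] <<- node$code
    parent[length(parent) + 1L] <<- par
    me <- length(code)
    for (ch in node$children) walk(ch, me)
  }
  walk(g, 0L)
  data.frame(code = code, parent = parent)
}

serialize_flat <- function(flat) {
  ser <- function(i) {
    kids <- which(flat$parent == i)
    kid_txt <- sort(vapply(kids, ser, ""))
    paste0("(", flat$code[i], paste0(kid_txt, collapse = ""), ")")
  }
  ser(which(flat$parent == 0L))
}

#' Simulate a glycan structure database
#'
#' Random N-glycan trees grown from the trimannosyl-chitobiose core by
#' attaching monosaccharide leaves at random nodes, deduplicated by
#' canonical string. The core itself is always entry 1.
#'
#' @param n_structures number of unique structures.
#' @param seed integer seed.
#' @param codes monosaccharide codes available for extension.
#' @param max_extra maximum number of added residues per structure.
#' @return character vector of canonical structure strings.
#' @export
simulate_glycan_db <- function(n_structures, seed = 1L,
                               codes = c("H", "N", "F", "A"), max_extra = 6L) {
  stopifnot(n_structures >= 1L)
  set.seed(seed)
  core_flat <- flatten_glycan(parse_glycan(N_GLYCAN_CORE))
  out <- N_GLYCAN_CORE
  guard <- 0L
  while (length(out) < n_structures && guard < 50L * n_structures) {
    guard <- guard + 1L
    flat <- core_flat
    for (j in seq_len(sample.int(max_extra, 1L))) {
      at <- sample.int(nrow(flat), 1L)
      flat <- rbind(flat, data.frame(code = sample(codes, 1L), parent = at))
    }
    out <- unique(c(out, serialize_flat(flat)))
  }
  out
}

#' Fucosylated variant of a glycan (entrapment construction)
#'
#' Replaces one hexose residue (preferring a leaf) with a fucose, giving a
#' glycan of different composition whose precursor lands in the same
#' isolation window for charge states 2+ and above (mass difference
#' 15.99 Da).
#'
#' @param struct canonical glycan structure string.
#' @return modified canonical string, or `NA` if the glycan has no hexose.
#' @export
glycan_fucose_variant <- function(struct) {
  flat <- flatten_glycan(parse_glycan(struct))
  is_h <- flat$code == "H"
  if (!any(is_h)) return(NA_character_)
  is_leaf <- !(seq_len(nrow(flat)) %in% flat$parent)
  pick <- if (any(is_h & is_leaf)) which(is_h & is_leaf)[1] else which(is_h)[1]
  flat$code[pick] <- "F"
  serialize_flat(flat)
}

KYTE_DOOLITTLE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
                    E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
                    M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, V = 4.2,
                    W = -0.9, Y = -1.3, J = -3.5)

random_sequon_peptide <- function(len_range = c(8L, 14L)) {
  pool <- c("A", "D", "E", "F", "G", "H", "I", "L", "M", "N", "Q", "S", "T",
            "V", "W", "Y")
  len <- sample(seq.int(len_range[1], len_range[2]), 1L)
  aa <- sample(pool, len, replace = TRUE)
  aa[len] <- sample(c("K", "R"), 1L)
  g <- sample.int(len - 3L, 1L)
  aa[g] <- "J"
  aa[g + 2L] <- sample(c("S", "T"), 1L)
  paste(aa, collapse = "")
}

sim_rt <- function(peptide, glycan_nodes) {
  aa <- strsplit(peptide, "", fixed = TRUE)[[1]]
  5 + 50 * stats::plogis(1.5 * mean(KYTE_DOOLITTLE[aa])) -
    0.3 * (glycan_nodes - 5)
}

pick_charge <- function(total_mass, mz_range = c(712.5, 1623.5)) {
  for (z in 2:5) {
    mz <- (total_mass + z * PROTON_MASS) / z
    if (mz >= mz_range[1] && mz <= mz_range[2]) return(z)
  }
  NA_integer_
}

#' Simulate DDA GPSMs and build their consensus library
#'
#' Tryptic-like peptides containing the N-X-S/T sequon (glycosite marked
#' `J`) are combined with glycans from a database; fragment intensities
#' follow a separable log-normal model (the peptide-part pattern depends
#' only on the peptide, the glycan-part pattern only on the glycan
#' composition), so KNN fragment swapping is learnable by construction.
#' RTs are a smooth hydrophobicity function of the peptide plus a
#' glycan-size offset. Spectra are generated at the theoretical fragment
#' m/z values with per-replicate intensity noise.
#'
#' @param n_peptides number of distinct peptides.
#' @param glycan_db character vector of structures (default: simulated db
#'   of 20 structures).
#' @param glycans_per_peptide how many database glycans each peptide
#'   carries.
#' @param replicates maximum GPSM replicates per precursor (drawn 1..max).
#' @param seed integer seed.
#' @param charge fixed charge state, or `NA` to pick the charge that puts
#'   the precursor inside the DIA window range.
#' @param rep_noise_sd log-intensity noise between replicates.
#' @param scheme isolation scheme used when building the library.
#' @return list with `gpsms` (list of GPSM lists), `library`
#'   (`glyco_library`) and `glycan_db`.
#' @export
simulate_library <- function(n_peptides = 12L, glycan_db = NULL,
                             glycans_per_peptide = 6L, replicates = 3L,
                             seed = 1L, charge = NA_integer_,
                             rep_noise_sd = 0.1,
                             scheme = default_isolation_scheme()) {
  set.seed(seed)
  if (is.null(glycan_db)) glycan_db <- simulate_glycan_db(20L, seed = seed + 1L,
                                                          codes = c("H", "N"))
  set.seed(seed)
  peptides <- character(0)
  while (length(peptides) < n_peptides)
    peptides <- unique(c(peptides, random_sequon_peptide()))
  pep_pattern <- new.env(parent = emptyenv())
  gly_pattern <- new.env(parent = emptyenv())
  pattern_for <- function(env, id, keys) {
    pat <- env[[id]]
    if (is.null(pat)) pat <- stats::setNames(numeric(0), character(0))
    new <- setdiff(keys, names(pat))
    if (length(new)) {
      pat <- c(pat, stats::setNames(stats::rlnorm(length(new), meanlog = 4, sdlog = 1), new))
      env[[id]] <- pat
    }
    pat[keys]
  }
  gpsms <- list()
  for (p in peptides) {
    gl <- sample(glycan_db, min(glycans_per_peptide, length(glycan_db)))
    for (g in gl) {
      theo <- theoretical_transitions(p, NULL, g)
      tm <- peptide_mass(p) + glycan_mass(g)
      z <- if (is.na(charge)) pick_charge(tm) else charge
      if (is.na(z)) next
      key <- transition_key(theo)
      base <- numeric(nrow(theo))
      pepsel <- theo$Part == "peptide"
      base[pepsel] <- pattern_for(pep_pattern, p, key[pepsel])
      comp <- composition_key(glycan_composition(g))
      base[!pepsel] <- pattern_for(gly_pattern, comp, key[!pepsel])
      rt0 <- sim_rt(p, glycan_node_count(parse_glycan(g)))
      for (r in seq_len(sample.int(replicates, 1L))) {
        inten <- base * exp(stats::rnorm(length(base), 0, rep_noise_sd))
        o <- order(theo$ProductMz)
        gpsms[[length(gpsms) + 1L]] <- list(
          peptide = p, mods = NULL, glycan = g, charge = z,
          total_score = stats::runif(1, 20, 40),
          rt = rt0 + stats::rnorm(1, 0, 0.05),
          run_id = paste0("dda_run", r),
          spectrum = data.frame(mz = theo$ProductMz[o], intensity = inten[o]))
      }
    }
  }
  lib <- build_library(gpsms, scheme = scheme, provenance = "simulated-dda")
  list(gpsms = gpsms, library = lib, glycan_db = glycan_db)
}

draw_subscores <- function(n, nonnull, separation, n_subscores, prefix) {
  m <- matrix(stats::rnorm(n * n_subscores), n, n_subscores)
  m[, 1] <- m[, 1] + separation * as.numeric(nonnull)
  colnames(m) <- paste0(prefix, c("coelution", "xcorr", "rt_dev", "mass_err")[seq_len(n_subscores)])
  m
}

#' Simulate four-class peak-group feature tables
#'
#' Target peak groups are drawn from the four joint peptide/glycan
#' correctness classes at the configured proportions; decoy classes follow
#' their theoretical mixtures (a glycan decoy is glycan-null with the
#' target's peptide-state mixture, and symmetrically), matching the
#' generative assumptions of the bivariate four-groups mixture model.
#' Sub-scores are Gaussian; the class separation (in within-class standard
#' deviations) is carried by the co-elution analogue of each axis.
#'
#' @param n_targets number of target peak groups (one candidate per
#'   queried precursor); the same number of each decoy class is drawn.
#' @param pi true class proportions `(pi00, pi01, pi10, pi11)`.
#' @param separation mean shift of non-null classes, in SD units.
#' @param n_subscores sub-scores per evidence axis (max 4).
#' @param seed integer seed.
#' @return feature data.frame with `label` and ground-truth columns
#'   `true_pep`, `true_gly`, `true_class`.
#' @export
simulate_peak_group_features <- function(n_targets = 5000L,
                                         pi = c(0.25, 0.15, 0.15, 0.45),
                                         separation = 3, n_subscores = 4L,
                                         seed = 1L) {
  stopifnot(length(pi) == 4L, abs(sum(pi) - 1) < 1e-8)
  set.seed(seed)
  classes <- c("00", "01", "10", "11")
  cls <- sample(classes, n_targets, replace = TRUE, prob = pi)
  t_pep <- cls %in% c("10", "11")
  t_gly <- cls %in% c("01", "11")
  pi_p_nonnull <- pi[3] + pi[4]
  pi_g_nonnull <- pi[2] + pi[4]
  block <- function(n, label, pep_nonnull, gly_nonnull) {
    data.frame(label = label,
               draw_subscores(n, pep_nonnull, separation, n_subscores, "pep_"),
               draw_subscores(n, gly_nonnull, separation, n_subscores, "gly_"),
               true_pep = pep_nonnull, true_gly = gly_nonnull,
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    block(n_targets, "target", t_pep, t_gly),
    block(n_targets, "glycan_decoy",
          stats::runif(n_targets) < pi_p_nonnull, rep(FALSE, n_targets)),
    block(n_targets, "peptide_decoy",
          rep(FALSE, n_targets), stats::runif(n_targets) < pi_g_nonnull),
    block(n_targets, "both_decoy", rep(FALSE, n_targets), rep(FALSE, n_targets)))
  n <- nrow(out)
  out$peak_group_id <- paste0("pg_", seq_len(n))
  out$precursor_id <- paste0(substr(out$label, 1, 1), "_prec_", seq_len(n))
  out$glycopeptide_id <- out$precursor_id
  out$run_id <- "run1"
  out$rt_apex <- stats::runif(n, 0, 60)
  out$true_class <- NA_character_
  out$true_class[out$label == "target"] <- cls
  rownames(out) <- NULL
  out
}

#' Simulate a glycan-entrapment benchmark
#'
#' Builds a target set of glycopeptide precursors carrying high-mannose
#' style glycans (H/N only) plus an equally sized entrapment set: the same
#' peptides carrying fucosylated variants (one hexose replaced by fucose,
#' 15.99 Da lighter, landing in the same isolation window at charge 2+).
#' Entrapment entries are targets in the library sense but their glycans
#' are absent from the sample: every peak group's extracted signal comes
#' from the analyte carrying the original (non-fucosylated) glycan, so
#' shared-core Y ions show signal for target and entrapment entries alike
#' and only the glycoform-discriminating transitions (and MS1/MS2
#' precursor evidence) can separate them. Peak-group features are
#' generated for both sets from the detectable (both-non-null) class.
#'
#' @param n_targets number of true target precursors (entrapment set has
#'   equal size).
#' @param separation class separation in SD units, used for both the
#'   peak-group sub-scores and the transition-level scores.
#' @param seed integer seed.
#' @param n_db number of glycan structures in the background database
#'   (fucosylated variants of all of them are added).
#' @param n_bg background glycoform cap per precursor.
#' @param scheme isolation scheme.
#' @param ms1_tol_ppm precursor m/z tolerance for the MS1/MS2-precursor
#'   evidence sets.
#' @param y_charges identification-transition charge states.
#' @return list with `entries` (precursor truth table), `features`
#'   (peak-group feature table for [score_peak_groups()]), `glycoform`
#'   (per-entry list: hypotheses, transition tables with simulated scores,
#'   decoy transitions, MS1 score), `glycan_db` and `scheme`.
#' @export
simulate_entrapment_benchmark <- function(n_targets = 2000L, separation = 3,
                                          seed = 1L, n_db = 120L, n_bg = 50L,
                                          scheme = default_isolation_scheme(),
                                          ms1_tol_ppm = 10,
                                          y_charges = 1:2) {
  set.seed(seed)
  db_hn <- simulate_glycan_db(n_db, seed = seed + 1L, codes = c("H", "N"),
                              max_extra = 5L)
  set.seed(seed)
  db_fuc <- unique(stats::na.omit(vapply(db_hn, glycan_fucose_variant, "")))
  glycan_db <- unique(c(db_hn, db_fuc))
  prepared_db <- prepare_glycan_db(glycan_db)
  peptides <- character(0)
  while (length(peptides) < n_targets)
    peptides <- unique(c(peptides, random_sequon_peptide()))
  rows <- list()
  same_window <- function(mz1, mz2) {
    # co-isolation under the first-matching-window rule, both directions
    w1 <- window_of(mz1, scheme); w2 <- window_of(mz2, scheme)
    !is.null(w1) && !is.null(w2) &&
      mz2 >= w1$lower && mz2 <= w1$upper && mz1 >= w2$lower && mz1 <= w2$upper
  }
  for (i in seq_len(n_targets)) {
    p <- peptides[i]
    pm <- peptide_mass(p)
    for (try in 1:10) {
      g_t <- sample(db_hn, 1L)
      g_e <- glycan_fucose_variant(g_t)
      if (is.na(g_e)) next
      z <- pick_charge(pm + glycan_mass(g_t))
      if (is.na(z)) next
      mz_t <- (pm + glycan_mass(g_t) + z * PROTON_MASS) / z
      mz_e <- (pm + glycan_mass(g_e) + z * PROTON_MASS) / z
      if (!same_window(mz_t, mz_e)) next
      rows[[length(rows) + 1L]] <- data.frame(
        entry_id = c(paste0("tgt_", i), paste0("ent_", i)),
        peptide = p, glycan = c(g_t, g_e), charge = z,
        true_glycan = g_t, entrapment = c(FALSE, TRUE),
        stringsAsFactors = FALSE)
      break
    }
  }
  entries <- do.call(rbind, rows)
  entries$precursor_mz <- mapply(function(p, g, z) glycopeptide_mz(p, g, z),
                                 entries$peptide, entries$glycan, entries$charge)
  rownames(entries) <- NULL
  n <- nrow(entries)
  # peak-group features: every library entry extracts a detectable peak
  # group (signal from the co-isolated true glycoform); plus decoy classes
  block <- function(ids, label, pep_nonnull, gly_nonnull) {
    m <- length(ids)
    data.frame(label = label,
               draw_subscores(m, pep_nonnull, separation, 4L, "pep_"),
               draw_subscores(m, gly_nonnull, separation, 4L, "gly_"),
               peak_group_id = paste0(label, "_", ids),
               precursor_id = paste0(label, "_", ids),
               glycopeptide_id = paste0(label, "_", ids),
               run_id = "run1", rt_apex = stats::runif(m, 0, 60),
               stringsAsFactors = FALSE)
  }
  features <- rbind(
    cbind(block(entries$entry_id, "target", TRUE, TRUE)),
    block(entries$entry_id, "peptide_decoy", FALSE, TRUE),
    block(entries$entry_id, "glycan_decoy", TRUE, FALSE),
    block(entries$entry_id, "both_decoy", FALSE, FALSE))
  features$peak_group_id <- sub("^target_", "", features$peak_group_id)
  features$precursor_id <- sub("^target_", "", features$precursor_id)
  features$glycopeptide_id <- sub("^target_", "", features$glycopeptide_id)
  # transition-level glycoform signals per library entry
  glycoform <- vector("list", n)
  names(glycoform) <- entries$entry_id
  for (i in seq_len(n)) {
    e <- entries[i, ]
    hyps <- select_background_glycoforms(e$peptide, "", e$glycan, e$charge,
                                         prepared_db, scheme, n_bg = n_bg)
    trans <- generate_identification_transitions(hyps, e$peptide, "",
                                                 charges = y_charges)
    true_keys <- enumerate_y_fragments(e$true_glycan)$keys
    true_mz <- glycopeptide_mz(e$peptide, e$true_glycan, e$charge)
    has_signal <- ifelse(
      trans$type == "y_ion",
      ifelse(trans$composition == "0", TRUE,
             trans$composition %in% true_keys),
      abs(trans$mz - true_mz) / true_mz * 1e6 <= ms1_tol_ppm)
    trans$score <- stats::rnorm(nrow(trans), separation * as.numeric(has_signal), 1)
    dec <- glycoform_decoy_transitions(e$peptide, "",
                                       setdiff(unique(unlist(lapply(hyps, `[[`, "fragment_keys"))), ""),
                                       charges = y_charges)
    dec$transitions$score <- stats::rnorm(nrow(dec$transitions), 0, 1)
    ms1_signal <- abs(e$precursor_mz - true_mz) / true_mz * 1e6 <= ms1_tol_ppm
    glycoform[[i]] <- list(
      hypotheses = hyps, transitions = trans,
      decoy_transitions = dec$transitions,
      ms1_score = stats::rnorm(1, separation * as.numeric(ms1_signal), 1),
      ms1_decoy_score = stats::rnorm(1, 0, 1))
  }
  list(entries = entries, features = features, glycoform = glycoform,
       glycan_db = glycan_db, scheme = scheme, ms1_tol_ppm = ms1_tol_ppm,
       separation = separation, seed = seed)
}
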