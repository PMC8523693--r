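# Independent oracles used across tests. These deliberately re-derive
# quantities by brute force or direct arithmetic, sharing as little code as
# possible with the implementation they check.

# Flatten a glycan tree into (code, parent) via its own traversal.
oracle_flatten <- function(struct) {
  g <- parse_glycan(struct)
  code <- character(0); parent <- integer(0)
  walk <- function(node, par) {
    code[length(code) + 1L] <<- node$code
    parent[length(parent) + 1L] <<- par
    me <- length(code)
    for (ch in node$children) walk(ch, me)
  }
  walk(g, 0L)
  list(code = code, parent = parent)
}

# Brute-force Y-fragment enumeration: all subsets of non-root nodes whose
# induced vertex set (plus root) is connected, keyed by composition.
oracle_y_fragments <- function(struct) {
  fl <- oracle_flatten(struct)
  n <- length(fl$code)
  keys <- ""
  others <- setdiff(seq_len(n), 1L)
  for (mask in 0:(2^length(others) - 1L)) {
    inset <- c(1L, others[bitwAnd(mask, 2^(seq_along(others) - 1L)) > 0])
    ok <- all(vapply(inset, function(i) i == 1L || fl$parent[i] %in% inset, TRUE))
    if (!ok) next
    counts <- table(fl$code[inset])
    keys <- c(keys, paste0(names(counts)[order(names(counts))],
                           as.integer(counts[order(names(counts))]),
                           collapse = ""))
  }
  sort(unique(keys))
}

# Direct (non-log-space) Bayes-table evaluation of the hierarchical model.
oracle_bhm <- function(hypotheses, pep_ms2, pep_ms1 = NA, in_tol = NULL,
                       pep_ms2_prec = NULL, transitions = NULL) {
  nh <- length(hypotheses)
  comps <- vapply(hypotheses, `[[`, "", "composition")
  n_comp <- length(unique(comps))
  prior <- c(pep_ms2,
             ((1 - pep_ms2) / n_comp) / as.vector(table(comps)[comps]))
  lik <- rep(1, nh + 1L)
  fl <- function(p) pmax(p, 1e-12)
  if (!is.na(pep_ms1)) {
    inM <- c(FALSE, in_tol)
    lik <- lik * fl(ifelse(inM, 1 - pep_ms1, pep_ms1))
  }
  if (!is.null(pep_ms2_prec)) {
    for (k in seq_len(nh)) {
      lik <- lik * fl(ifelse(c(FALSE, seq_len(nh) == k),
                             1 - pep_ms2_prec[k], pep_ms2_prec[k]))
    }
  }
  p_g <- prior * lik
  p_g <- p_g / sum(p_g)
  tlik <- rep(1, nh + 1L)
  if (!is.null(transitions) && nrow(transitions)) {
    for (j in seq_len(nrow(transitions))) {
      member <- c(FALSE, seq_len(nh) %in% transitions$hypotheses[[j]])
      tlik <- tlik * fl(ifelse(member, 1 - transitions$pep[j], transitions$pep[j]))
    }
  }
  p_g_t <- p_g * tlik
  p_g_t <- p_g_t / sum(p_g_t)
  list(prior = prior, p_g = p_g, p_g_t = p_g_t)
}

# Minimal hypothesis constructor for BHM tests.
make_hyp <- function(composition, fragment_keys = character(0),
                     precursor_mz = 1000, is_target = FALSE,
                     structures = composition) {
  list(structures = structures, composition = composition,
       fragment_keys = fragment_keys, precursor_mz = precursor_mz,
       is_target = is_target)
}

# A tiny deterministic spectral library built in code (no fixtures on disk):
# every peptide carries every glycan so KNN neighborhoods are dense.
toy_library <- function(n_peptides = 6L, n_glycans = 5L, seed = 42L) {
  db <- simulate_glycan_db(n_glycans, seed = seed, codes = c("H", "N"))
  sim <- simulate_library(n_peptides = n_peptides, glycan_db = db,
                          glycans_per_peptide = n_glycans, replicates = 1L,
                          seed = seed, charge = 3L)
  sim$library
}
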