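#' Glycopeptide spectral libraries
#'
#' A library is a pair of tables: one row per glycopeptide precursor
#' (peptide, modifications, glycan structure, charge) and one row per
#' annotated transition. Column naming follows OpenSWATH assay-library
#' conventions where one exists. Transitions belong to the peptide part
#' (b/y series and their HexNAc / cross-ring variants) or the glycan part
#' (Y series, including Y0 and the cross-ring fragment `Y$`).
#'
#' Fragment composition encoding in the `FragmentComposition` column:
#' `"0"` for Y0 (naked peptide), `"$"` for the cross-ring fragment, a
#' composition key (e.g. `"H3N2"`) for other Y ions, and `NA` for
#' backbone ions.
#'
#' @name glyco_library
NULL

#' Construct a spectral library object
#'
#' @param precursors data.frame with columns `PrecursorId`, `Peptide`,
#'   `Modifications`, `GlycanStructure`, `GlycanComposition`, `Charge`,
#'   `PrecursorMz`, `NormalizedRetentionTime`, `ReplicateCount`, `SumScore`,
#'   `Provenance`, `IsDecoy`, `DecoyType`.
#' @param transitions data.frame with columns `PrecursorId`, `FragmentType`,
#'   `FragmentSeriesNumber`, `FragmentComposition`, `FragmentCharge`,
#'   `ProductMz`, `LibraryIntensity`, `Part`, `IsQuantifier`.
#' @return an object of class `glyco_library`.
#' @export
glyco_library <- function(precursors, transitions) {
  req_p <- c("PrecursorId", "Peptide", "Modifications", "GlycanStructure",
             "GlycanComposition", "Charge", "PrecursorMz",
             "NormalizedRetentionTime", "ReplicateCount", "SumScore",
             "Provenance", "IsDecoy", "DecoyType")
  req_t <- c("PrecursorId", "FragmentType", "FragmentSeriesNumber",
             "FragmentComposition", "FragmentCharge", "ProductMz",
             "LibraryIntensity", "Part", "IsQuantifier")
  miss <- setdiff(req_p, names(precursors))
  if (length(miss)) stop("library precursor table missing column(s): ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(req_t, names(transitions))
  if (length(miss)) stop("library transition table missing column(s): ",
                         paste(miss, collapse = ", "))
  structure(list(precursors = precursors[req_p], transitions = transitions[req_t]),
            class = "glyco_library")
}

#' @export
print.glyco_library <- function(x, ...) {
  cat("<glyco_library> ", nrow(x$precursors), " precursors (",
      sum(!x$precursors$IsDecoy), " targets), ",
      nrow(x$transitions), " transitions\n", sep = "")
  invisible(x)
}

#' An empty spectral library
#' @return a `glyco_library` with zero entries.
#' @export
empty_library <- function() {
  glyco_library(
    data.frame(PrecursorId = character(), Peptide = character(),
               Modifications = character(), GlycanStructure = character(),
               GlycanComposition = character(), Charge = integer(),
               PrecursorMz = numeric(), NormalizedRetentionTime = numeric(),
               ReplicateCount = integer(), SumScore = numeric(),
               Provenance = character(), IsDecoy = logical(),
               DecoyType = character(), stringsAsFactors = FALSE),
    data.frame(PrecursorId = character(), FragmentType = character(),
               FragmentSeriesNumber = integer(), FragmentComposition = character(),
               FragmentCharge = integer(), ProductMz = numeric(),
               LibraryIntensity = numeric(), Part = character(),
               IsQuantifier = logical(), stringsAsFactors = FALSE))
}

#' Format / parse positional modifications
#'
#' Modifications travel in tables as `"delta@position"` terms joined by
#' `";"`, e.g. `"57.02146@3;15.99491@7"`.
#'
#' @param mods data.frame with columns `position`, `delta`, or a string.
#' @return `format_mods()` a single string; `parse_mods()` a data.frame.
#' @export
format_mods <- function(mods) {
  if (is.null(mods) || NROW(mods) == 0L) return("")
  o <- order(mods$position)
  paste(sprintf("%.5f@%d", mods$delta[o], as.integer(mods$position[o])), collapse = ";")
}

#' @rdname format_mods
#' @export
parse_mods <- function(mods) {
  if (is.null(mods) || is.na(mods) || !nzchar(mods))
    return(data.frame(position = integer(), delta = numeric()))
  parts <- strsplit(strsplit(mods, ";", fixed = TRUE)[[1]], "@", fixed = TRUE)
  data.frame(position = vapply(parts, function(p) as.integer(p[2]), 0L),
             delta = vapply(parts, function(p) as.numeric(p[1]), 0))
}

#' Canonical precursor identifier
#' @param peptide,mods,glycan,charge precursor coordinates (`mods` a
#'   data.frame or pre-formatted string; `glycan` canonical structure text).
#' @return single id string.
#' @export
precursor_id <- function(peptide, mods, glycan, charge) {
  ms <- if (is.character(mods)) mods else format_mods(mods)
  paste(peptide, ms, glycan, charge, sep = "/")
}

#' Mass of a retained glycan fragment given its encoded composition
#' @param comp `"0"` (Y0), `"$"` (cross-ring), or composition key.
#' @param crossring_mass cross-ring offset in Da.
#' @param registry monosaccharide registry.
#' @return mass in Da.
#' @export
fragment_composition_mass <- function(comp, crossring_mass = CROSSRING_MASS,
                                      registry = monosaccharide_masses()) {
  vapply(comp, function(k) {
    if (k == "0") 0
    else if (k == "$") crossring_mass
    else glycan_mass(parse_composition_key(k, registry), registry)
  }, 0, USE.NAMES = FALSE)
}

transition_key <- function(tr) {
  paste(tr$FragmentType,
        ifelse(is.na(tr$FragmentSeriesNumber), "", tr$FragmentSeriesNumber),
        ifelse(is.na(tr$FragmentComposition), "", tr$FragmentComposition),
        tr$FragmentCharge, sep = "|")
}

#' Theoretical transitions of a glycopeptide precursor
#'
#' Generates the full in-silico fragment list matched during annotation:
#' Y ions (including Y0 and `Y$`) at charges 1-3, b/y at charges 1-2, and
#' b/y with one HexNAc (`b-N1`/`y-N1`) or the HexNAc cross-ring fragment
#' (`b$`/`y$`) at charges 1-2 for glycosite-containing fragments.
#'
#' @param peptide amino-acid string with `J` marker.
#' @param mods modification data.frame (or string).
#' @param glycan glycan structure text or `glycan_struct`.
#' @param registry monosaccharide registry.
#' @param crossring_mass cross-ring offset in Da.
#' @return transition data.frame (no intensities).
#' @export
theoretical_transitions <- function(peptide, mods, glycan,
                                    registry = monosaccharide_masses(),
                                    crossring_mass = CROSSRING_MASS) {
  if (is.character(mods)) mods <- parse_mods(mods)
  pm <- peptide_mass(peptide, mods)
  fs <- enumerate_y_fragments(glycan, registry)
  comps <- c("0", "$", setdiff(fs$keys, ""))
  gmass <- fragment_composition_mass(comps, crossring_mass, registry)
  ych <- 1:3
  y_tab <- data.frame(
    FragmentType = "Y",
    FragmentSeriesNumber = NA_integer_,
    FragmentComposition = rep(comps, each = length(ych)),
    FragmentCharge = rep(ych, times = length(comps)),
    ProductMz = as.vector(vapply(seq_along(comps), function(i)
      y_ion_mz(pm, gmass[i], ych), numeric(length(ych)))),
    Part = "glycan", stringsAsFactors = FALSE)

  n <- nchar(peptide)
  types <- c("b", "y", "b-N1", "y-N1", "b$", "y$")
  grids <- expand.grid(FragmentType = types, FragmentSeriesNumber = seq_len(n - 1L),
                       FragmentCharge = 1:2, stringsAsFactors = FALSE)
  grids$ProductMz <- mapply(function(ty, o, z)
    backbone_fragment_mz(peptide, ty, o, z, mods, crossring_mass),
    grids$FragmentType, grids$FragmentSeriesNumber, grids$FragmentCharge)
  grids <- grids[!is.na(grids$ProductMz), , drop = FALSE]
  grids$FragmentComposition <- NA_character_
  grids$Part <- "peptide"
  out <- rbind(y_tab, grids[names(y_tab)])
  rownames(out) <- NULL
  out
}

#' Annotate a GPSM spectrum with theoretical fragments
#'
#' Each theoretical fragment claims the nearest observed peak within the
#' ppm tolerance; unmatched fragments are dropped.
#'
#' @param gpsm list with fields `peptide`, `mods` (data.frame or string),
#'   `glycan` (canonical text), `charge`, `spectrum` (data.frame with
#'   columns `mz`, `intensity`, m/z ascending).
#' @param tol_ppm fragment match tolerance in ppm (default 20).
#' @param registry monosaccharide registry.
#' @param crossring_mass cross-ring offset in Da.
#' @return annotated transition data.frame with `LibraryIntensity`.
#' @export
annotate_spectrum <- function(gpsm, tol_ppm = 20,
                              registry = monosaccharide_masses(),
                              crossring_mass = CROSSRING_MASS) {
  theo <- theoretical_transitions(gpsm$peptide, gpsm$mods, gpsm$glycan,
                                  registry, crossring_mass)
  sp <- gpsm$spectrum
  if (is.null(sp) || nrow(sp) == 0L) {
    theo$LibraryIntensity <- numeric(0)
    return(theo[integer(0), ])
  }
  idx <- findInterval(theo$ProductMz, sp$mz)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, nrow(sp))
  d_lo <- abs(sp$mz[lo] - theo$ProductMz)
  d_hi <- abs(sp$mz[hi] - theo$ProductMz)
  nearest <- ifelse(d_lo <= d_hi, lo, hi)
  ppm <- abs(sp$mz[nearest] - theo$ProductMz) / theo$ProductMz * 1e6
  keep <- ppm <= tol_ppm
  theo <- theo[keep, , drop = FALSE]
  theo$LibraryIntensity <- sp$intensity[nearest[keep]]
  rownames(theo) <- NULL
  theo
}

#' Keep GPSMs of the highest-scoring glycan structure
#'
#' GPSMs of one glycopeptide precursor may be annotated with different
#' plausible glycan structures; per structure, the identification scores
#' are summed and only GPSMs carrying the top-sum structure are kept.
#' Exact ties are broken by canonical structure string order.
#'
#' @param gpsms list of GPSM lists sharing (peptide, mods, glycan
#'   composition, charge); each has fields `glycan` and `total_score`.
#' @return the subset of `gpsms` annotated with the winning structure.
#' @export
select_best_structure <- function(gpsms) {
  if (!length(gpsms)) stop("no GPSMs given")
  structs <- vapply(gpsms, function(g) serialize_glycan(parse_glycan(g$glycan)), "")
  scores <- vapply(gpsms, function(g) g$total_score, 0)
  sums <- tapply(scores, structs, sum)
  best <- names(sums)[order(-sums, names(sums))][1]
  gpsms[structs == best]
}

cosine_dp <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Build a consensus transition list from replicate annotations
#'
#' Replicates are aligned by annotation identity (fragment type, ordinal or
#' composition, charge). Dissimilar replicates (median pairwise dot product
#' to the others below `min_median_dp`) are discarded; if all replicates
#' are mutually dissimilar, the single highest-scoring replicate is kept.
#' Only peaks present in strictly more than `presence` of the surviving
#' replicates are retained; consensus m/z and intensities are means
#' weighted by identification score.
#'
#' @param replicates list of annotated transition data.frames.
#' @param scores identification scores, one per replicate.
#' @param min_median_dp dissimilar-replicate threshold (default 0.5).
#' @param presence strict presence fraction (default 0.6).
#' @return list with `transitions` (consensus data.frame) and `used`
#'   (logical vector of surviving replicates).
#' @export
build_consensus <- function(replicates, scores, min_median_dp = 0.5,
                            presence = 0.6) {
  stopifnot(length(replicates) >= 1L, length(scores) == length(replicates))
  n <- length(replicates)
  if (n > 1L) {
    keys <- lapply(replicates, transition_key)
    all_keys <- unique(unlist(keys))
    mat <- vapply(seq_len(n), function(i) {
      v <- numeric(length(all_keys))
      v[match(keys[[i]], all_keys)] <- replicates[[i]]$LibraryIntensity
      v
    }, numeric(length(all_keys)))
    dp <- matrix(1, n, n)
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      dp[i, j] <- dp[j, i] <- cosine_dp(mat[, i], mat[, j])
    }
    med <- vapply(seq_len(n), function(i) stats::median(dp[i, -i]), 0)
    used <- med >= min_median_dp
    if (!any(used)) used <- seq_len(n) == which.max(scores)
  } else used <- TRUE
  reps <- replicates[used]
  sc <- scores[used]
  tall <- do.call(rbind, reps)
  tall$.key <- transition_key(tall)
  tall$.w <- rep(sc, vapply(reps, nrow, 0L))
  cnt <- table(tall$.key)
  keep_keys <- names(cnt)[cnt > presence * length(reps)]
  tall <- tall[tall$.key %in% keep_keys, , drop = FALSE]
  if (!nrow(tall)) {
    out <- replicates[[1]][integer(0), ]
    return(list(transitions = out, used = used))
  }
  agg <- function(x, w) sum(x * w) / sum(w)
  sp <- split(seq_len(nrow(tall)), tall$.key)
  rows <- lapply(sp, function(ii) {
    r <- tall[ii[1], setdiff(names(tall), c(".key", ".w")), drop = FALSE]
    r$ProductMz <- agg(tall$ProductMz[ii], tall$.w[ii])
    r$LibraryIntensity <- agg(tall$LibraryIntensity[ii], tall$.w[ii])
    r
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$ProductMz), , drop = FALSE]
  rownames(out) <- NULL
  list(transitions = out, used = used)
}

#' DIA isolation scheme
#'
#' @param centers window centers in Da.
#' @param width common window width in Da.
#' @return data.frame with `center`, `lower`, `upper`.
#' @export
isolation_scheme <- function(centers, width) {
  data.frame(center = centers, lower = centers - width / 2,
             upper = centers + width / 2)
}

#' Default isolation scheme: 40 windows, centers 700-1636 Da, 25 Da wide,
#' 1 Da overlap.
#' @return data.frame as in [isolation_scheme()].
#' @export
default_isolation_scheme <- function() {
  isolation_scheme(seq(700, 1636, by = 24), 25)
}

window_of <- function(mz, scheme) {
  hit <- which(mz >= scheme$lower & mz <= scheme$upper)
  if (!length(hit)) return(NULL)
  scheme[hit[1], , drop = FALSE]
}

#' Filter and rank the transitions of one library entry
#'
#' Excludes fragments outside the MS2 scan range or inside the precursor's
#' own isolation window, keeps the top 10 peptide-part and top 10
#' glycan-part transitions by intensity (intensity ties broken by ascending
#' m/z), flags the top 6 + 6 as quantifiers, and drops the entry when fewer
#' than 3 transitions remain on either part.
#'
#' @param transitions annotated transition data.frame.
#' @param precursor_mz precursor m/z in Da.
#' @param scan_range numeric length-2 MS2 scan range in Da.
#' @param scheme isolation scheme data.frame (see [isolation_scheme()]).
#' @param max_per_part,quantify_per_part,min_per_part filter parameters.
#' @return filtered transition data.frame, or `NULL` when the entry fails
#'   the minimum-transition rule.
#' @export
filter_transitions <- function(transitions, precursor_mz,
                               scan_range = c(200, 2000),
                               scheme = default_isolation_scheme(),
                               max_per_part = 10L, quantify_per_part = 6L,
                               min_per_part = 3L) {
  tr <- transitions
  keep <- tr$ProductMz >= scan_range[1] & tr$ProductMz <= scan_range[2]
  # a precursor near a window edge is co-isolated by both overlapping
  # windows; fragments inside any window containing it are excluded
  for (w in which(precursor_mz >= scheme$lower & precursor_mz <= scheme$upper)) {
    keep <- keep & !(tr$ProductMz >= scheme$lower[w] & tr$ProductMz <= scheme$upper[w])
  }
  tr <- tr[keep, , drop = FALSE]
  pick <- function(part) {
    sub <- tr[tr$Part == part, , drop = FALSE]
    sub <- sub[order(-sub$LibraryIntensity, sub$ProductMz), , drop = FALSE]
    sub <- utils::head(sub, max_per_part)
    sub$IsQuantifier <- seq_len(nrow(sub)) <= quantify_per_part
    sub
  }
  pep <- pick("peptide"); gly <- pick("glycan")
  if (nrow(pep) < min_per_part || nrow(gly) < min_per_part) return(NULL)
  out <- rbind(pep, gly)
  out <- out[order(out$ProductMz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Calibrate retention times against anchor identifications
#'
#' Fits a LOWESS curve through anchor pairs (shared identifications between
#' a source run and the target gradient) and maps arbitrary RTs through it
#' by interpolation; outside the anchor range the boundary value is used.
#'
#' @param anchors data.frame with columns `rt_source`, `rt_target` (minutes).
#' @param rts RT values (minutes, source scale) to calibrate.
#' @param min_anchors minimum number of anchor pairs (default 10).
#' @param span LOWESS smoother span (default 2/3).
#' @param iterations LOWESS robustness iterations (default 3).
#' @return calibrated RT vector (minutes, target scale).
#' @export
calibrate_rt <- function(anchors, rts, min_anchors = 10L, span = 2 / 3,
                         iterations = 3L) {
  if (NROW(anchors) < min_anchors)
    stop("need at least ", min_anchors, " anchor pairs, got ", NROW(anchors))
  fit <- stats::lowess(anchors$rt_source, anchors$rt_target, f = span,
                       iter = iterations)
  stats::approx(fit$x, fit$y, xout = rts, rule = 2, ties = mean)$y
}

#' Calibrate a library's retention times and export the anchors
#'
#' Applies [calibrate_rt()] to every entry of a library and optionally
#' writes the anchor entries' transitions as a TraML file for use as
#' reference glycopeptides during chromatographic extraction.
#'
#' @param lib a `glyco_library` on the source RT scale.
#' @param anchors data.frame with columns `rt_source`, `rt_target` and
#'   optionally `PrecursorId` (required for TraML export).
#' @param traml_path optional output path for the anchor TraML.
#' @param ... passed to [calibrate_rt()].
#' @return the library with calibrated `NormalizedRetentionTime`.
#' @export
calibrate_library_rt <- function(lib, anchors, traml_path = NULL, ...) {
  stopifnot(inherits(lib, "glyco_library"))
  lib$precursors$NormalizedRetentionTime <-
    calibrate_rt(anchors, lib$precursors$NormalizedRetentionTime, ...)
  if (!is.null(traml_path)) {
    if (is.null(anchors$PrecursorId))
      stop("anchor export requires a PrecursorId column in `anchors`")
    sel <- lib$precursors$PrecursorId %in% anchors$PrecursorId
    export_anchors_traml(
      glyco_library(lib$precursors[sel, , drop = FALSE],
                    lib$transitions[lib$transitions$PrecursorId %in%
                                      anchors$PrecursorId, , drop = FALSE]),
      traml_path)
  }
  lib
}

#' Merge spectral libraries
#'
#' Entries are unioned; duplicate precursor ids are resolved by preferring
#' the higher replicate count, then the higher summed identification score,
#' then the newest provenance (later library in the argument list).
#'
#' @param ... `glyco_library` objects (or a single list of them).
#' @return merged `glyco_library`.
#' @export
merge_libraries <- function(...) {
  libs <- list(...)
  if (length(libs) == 1L && !inherits(libs[[1]], "glyco_library")) libs <- libs[[1]]
  stopifnot(all(vapply(libs, inherits, TRUE, "glyco_library")))
  prec <- do.call(rbind, lapply(seq_along(libs), function(i) {
    p <- libs[[i]]$precursors
    p$.origin <- rep(i, nrow(p))
    p
  }))
  if (!nrow(prec)) return(empty_library())
  trans <- do.call(rbind, lapply(seq_along(libs), function(i) {
    t <- libs[[i]]$transitions
    t$.origin <- rep(i, nrow(t))
    t
  }))
  o <- order(prec$PrecursorId, -prec$ReplicateCount, -prec$SumScore, -prec$.origin)
  prec <- prec[o, , drop = FALSE]
  prec <- prec[!duplicated(prec$PrecursorId), , drop = FALSE]
  key_t <- paste(trans$PrecursorId, trans$.origin)
  key_p <- paste(prec$PrecursorId, prec$.origin)
  trans <- trans[key_t %in% key_p, , drop = FALSE]
  prec$.origin <- NULL
  trans$.origin <- NULL
  rownames(prec) <- rownames(trans) <- NULL
  glyco_library(prec, trans)
}

#' Build a consensus spectral library from DDA GPSMs
#'
#' Full library-building pipeline: group GPSMs by glycopeptide precursor
#' (peptide, modifications, glycan composition, charge), keep the
#' highest-sum-score glycan structure per precursor, annotate each GPSM
#' spectrum, build consensus transition lists across replicates, apply the
#' transition filters, and assemble the library.
#'
#' @param gpsms list of GPSM lists with fields `peptide`, `mods`, `glycan`,
#'   `charge`, `total_score`, `rt`, `run_id`, `spectrum`.
#' @param tol_ppm annotation tolerance in ppm.
#' @param scan_range MS2 scan range in Da.
#' @param scheme isolation scheme.
#' @param provenance provenance label recorded per entry.
#' @param registry monosaccharide registry.
#' @param crossring_mass cross-ring offset in Da.
#' @return a `glyco_library`.
#' @export
build_library <- function(gpsms, tol_ppm = 20, scan_range = c(200, 2000),
                          scheme = default_isolation_scheme(),
                          provenance = "dda",
                          registry = monosaccharide_masses(),
                          crossring_mass = CROSSRING_MASS) {
  if (!length(gpsms)) return(empty_library())
  grp_key <- vapply(gpsms, function(g) {
    comp <- composition_key(glycan_composition(g$glycan, registry))
    paste(g$peptide, format_mods(if (is.character(g$mods)) parse_mods(g$mods) else g$mods),
          comp, g$charge, sep = "/")
  }, "")
  prec_rows <- list(); trans_rows <- list()
  for (key in unique(grp_key)) {
    grp <- gpsms[grp_key == key]
    grp <- select_best_structure(grp)
    g1 <- grp[[1]]
    mods <- if (is.character(g1$mods)) parse_mods(g1$mods) else g1$mods
    struct <- serialize_glycan(parse_glycan(g1$glycan, registry))
    ann <- lapply(grp, annotate_spectrum, tol_ppm = tol_ppm,
                  registry = registry, crossring_mass = crossring_mass)
    has <- vapply(ann, nrow, 0L) > 0L
    if (!any(has)) next
    ann <- ann[has]; grp <- grp[has]
    scores <- vapply(grp, function(g) g$total_score, 0)
    cons <- build_consensus(ann, scores)
    pmz <- glycopeptide_mz(g1$peptide, struct, g1$charge, mods)
    tr <- filter_transitions(cons$transitions, pmz, scan_range, scheme)
    if (is.null(tr)) next
    used_scores <- scores[cons$used]
    used_rts <- vapply(grp[cons$used], function(g) g$rt, 0)
    pid <- precursor_id(g1$peptide, mods, struct, g1$charge)
    tr$PrecursorId <- pid
    prec_rows[[length(prec_rows) + 1L]] <- data.frame(
      PrecursorId = pid, Peptide = g1$peptide, Modifications = format_mods(mods),
      GlycanStructure = struct,
      GlycanComposition = composition_key(glycan_composition(struct, registry)),
      Charge = as.integer(g1$charge), PrecursorMz = pmz,
      NormalizedRetentionTime = sum(used_rts * used_scores) / sum(used_scores),
      ReplicateCount = length(used_scores), SumScore = sum(scores),
      Provenance = provenance, IsDecoy = FALSE, DecoyType = "",
      stringsAsFactors = FALSE)
    trans_rows[[length(trans_rows) + 1L]] <- tr
  }
  if (!length(prec_rows)) return(empty_library())
  glyco_library(do.call(rbind, prec_rows), do.call(rbind, trans_rows))
}
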