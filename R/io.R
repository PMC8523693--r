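#' Table input/output
#'
#' TSV is the canonical interchange format; floating-point columns are
#' written with 17 significant digits so every table round-trips exactly.
#' Anchor transitions are exported as TraML for downstream chromatographic
#' extraction tools.
#'
#' @name io
NULL

format_table <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      v <- sprintf("%.17g", df[[j]])
      v[is.na(df[[j]])] <- ""
      df[[j]] <- v
    }
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(format_table(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "", ...)
}

require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " is missing required column(s): ", paste(miss, collapse = ", "))
  invisible(df)
}

#' Write / read a spectral library TSV
#'
#' One row per transition, precursor-level fields repeated
#' (OpenSWATH-style column naming).
#'
#' @param lib a `glyco_library`.
#' @param path file path.
#' @return `read_library()` returns a `glyco_library`.
#' @export
write_library <- function(lib, path) {
  stopifnot(inherits(lib, "glyco_library"))
  flat <- merge(lib$transitions, lib$precursors, by = "PrecursorId", sort = FALSE)
  write_tsv(flat, path)
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  flat <- read_tsv(path, colClasses = c(Modifications = "character",
                                        FragmentComposition = "character",
                                        GlycanComposition = "character",
                                        DecoyType = "character"))
  require_columns(flat, c("PrecursorId", "Peptide", "GlycanStructure", "Charge",
                          "PrecursorMz", "ProductMz", "LibraryIntensity"),
                  "library table")
  flat$Modifications[is.na(flat$Modifications)] <- ""
  flat$DecoyType[is.na(flat$DecoyType)] <- ""
  prec_cols <- c("PrecursorId", "Peptide", "Modifications", "GlycanStructure",
                 "GlycanComposition", "Charge", "PrecursorMz",
                 "NormalizedRetentionTime", "ReplicateCount", "SumScore",
                 "Provenance", "IsDecoy", "DecoyType")
  trans_cols <- c("PrecursorId", "FragmentType", "FragmentSeriesNumber",
                  "FragmentComposition", "FragmentCharge", "ProductMz",
                  "LibraryIntensity", "Part", "IsQuantifier")
  prec <- flat[!duplicated(flat$PrecursorId), prec_cols, drop = FALSE]
  rownames(prec) <- NULL
  glyco_library(prec, flat[trans_cols])
}

#' Write / read a peak-group feature TSV
#'
#' @param features feature data.frame (see [score_peak_groups()]).
#' @param path file path.
#' @export
write_features <- function(features, path) {
  write_tsv(features, path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- read_tsv(path)
  require_columns(df, c("peak_group_id", "precursor_id", "run_id", "rt_apex",
                        "label"), "feature table")
  if (!any(grepl("^pep_", names(df))) || !any(grepl("^gly_", names(df))))
    stop("feature table is missing required column(s): pep_* / gly_* sub-scores")
  df
}

#' Write / read a glycan structure database
#'
#' One canonical structure string per line with its composition key.
#'
#' @param structures character vector of canonical structure strings.
#' @param path file path.
#' @export
write_glycan_db <- function(structures, path) {
  comp <- vapply(structures, function(s)
    composition_key(glycan_composition(s)), "")
  write_tsv(data.frame(GlycanStructure = structures, GlycanComposition = comp,
                       stringsAsFactors = FALSE), path)
  invisible(path)
}

#' @rdname write_glycan_db
#' @export
read_glycan_db <- function(path) {
  df <- read_tsv(path)
  require_columns(df, "GlycanStructure", "glycan database")
  df$GlycanStructure
}

#' Export anchor transitions as TraML
#'
#' Writes a minimal TraML 1.0.0 document: one compound per anchor
#' precursor (with its retention time) and one transition element per
#' library transition.
#'
#' @param anchors a `glyco_library` holding the anchor entries.
#' @param path output file path.
#' @export
export_anchors_traml <- function(anchors, path) {
  stopifnot(inherits(anchors, "glyco_library"))
  doc <- xml2::xml_new_root(
    "TraML", version = "1.0.0",
    xmlns = "http://psi.hupo.org/ms/traml")
  cl <- xml2::xml_add_child(doc, "CompoundList")
  prec <- anchors$precursors
  for (i in seq_len(nrow(prec))) {
    p <- prec[i, ]
    pep <- xml2::xml_add_child(cl, "Peptide", id = p$PrecursorId,
                               sequence = gsub("J", "N", p$Peptide))
    rt_l <- xml2::xml_add_child(pep, "RetentionTimeList")
    rt <- xml2::xml_add_child(rt_l, "RetentionTime")
    xml2::xml_add_child(rt, "cvParam", cvRef = "MS", accession = "MS:1000895",
                        name = "local retention time",
                        value = sprintf("%.6f", p$NormalizedRetentionTime),
                        unitAccession = "UO:0000031", unitName = "minute")
  }
  tl <- xml2::xml_add_child(doc, "TransitionList")
  trans <- anchors$transitions
  for (i in seq_len(nrow(trans))) {
    tr <- trans[i, ]
    p <- prec[match(tr$PrecursorId, prec$PrecursorId), ]
    node <- xml2::xml_add_child(tl, "Transition",
                                id = paste0(tr$PrecursorId, "_", i),
                                peptideRef = tr$PrecursorId)
    pr <- xml2::xml_add_child(node, "Precursor")
    xml2::xml_add_child(pr, "cvParam", cvRef = "MS", accession = "MS:1000827",
                        name = "isolation window target m/z",
                        value = sprintf("%.6f", p$PrecursorMz))
    pd <- xml2::xml_add_child(node, "Product")
    xml2::xml_add_child(pd, "cvParam", cvRef = "MS", accession = "MS:1000827",
                        name = "isolation window target m/z",
                        value = sprintf("%.6f", tr$ProductMz))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Default pipeline configuration
#'
#' Tolerances, isolation scheme, report thresholds and search parameters
#' with their standard defaults: MS1 10 ppm, MS2 20 ppm, 40 isolation
#' windows of 25 Da with 1 Da overlap covering 700-1636 Da centers, run
#' q-value 0.05, best-run and global q-values 0.01, glycoform q-values
#' 0.05 per run / 0.01 best run, KNN k = 3, and 50 background glycoforms.
#'
#' @param ... named overrides.
#' @return named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    ms1_tol_ppm = 10, ms2_tol_ppm = 20,
    window_centers = seq(700, 1636, by = 24), window_width = 25,
    scan_range = c(200, 2000),
    run_q = 0.05, best_run_q = 0.01, global_q = 0.01,
    glycoform_run_q = 0.05, glycoform_best_q = 0.01,
    knn_k = 3L, n_bg = 50L, lambda = 0.4, seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  for (f in c("run_q", "best_run_q", "global_q", "glycoform_run_q", "glycoform_best_q"))
    if (cfg[[f]] <= 0 || cfg[[f]] > 1) stop("threshold ", f, " must be in (0, 1]")
  cfg
}

#' Read a YAML configuration file
#' @param path YAML file; fields override [pipeline_config()] defaults.
#' @return configuration list.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read configuration files")
  do.call(pipeline_config, yaml::read_yaml(path))
}
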