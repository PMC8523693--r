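#' Hierarchical glycopeptide quantification
#'
#' Peak-group intensity matrices (rows = peak groups, columns = runs;
#' missing values are `NA`, never zero) are median-normalized per run and
#' aggregated up the identity hierarchy: peak groups to glycopeptides
#' (same peptide sequence and glycan composition; sum of the 3 most
#' intense peak groups per sample), glycopeptides to site-specific glycans
#' (sum of the 3 most intense glycopeptides), and site-specific glycans to
#' protein glycosites (sum of all).
#'
#' @name quantification
NULL

#' Median-normalize an intensity matrix
#'
#' Each run (column) is scaled so that its median over non-missing values
#' equals the grand median of the run medians.
#'
#' @param mat numeric matrix, `NA` for missing.
#' @return normalized matrix.
#' @export
median_normalize <- function(mat) {
  meds <- apply(mat, 2, stats::median, na.rm = TRUE)
  if (any(is.na(meds)))
    stop("run(s) with no non-missing values: ",
         paste(colnames(mat)[is.na(meds)], collapse = ", "))
  target <- stats::median(meds)
  sweep(mat, 2, target / meds, `*`)
}

top_n_colsum <- function(mat, n = 3L) {
  apply(mat, 2, function(col) {
    v <- col[!is.na(col)]
    if (!length(v)) return(NA_real_)
    sum(sort(v, decreasing = TRUE)[seq_len(min(n, length(v)))])
  })
}

#' Aggregate an intensity matrix one level up the hierarchy
#'
#' @param mat numeric matrix with rownames identifying the lower-level
#'   analytes.
#' @param mapping character vector (parallel to `rownames(mat)`) giving
#'   each row's parent analyte.
#' @param top number of most intense members summed per sample; `Inf`
#'   sums all members (the protein-glycosite rule). Top membership is
#'   recomputed per sample (column-wise).
#' @return matrix with one row per parent analyte.
#' @export
aggregate_intensities <- function(mat, mapping, top = 3L) {
  stopifnot(length(mapping) == nrow(mat))
  groups <- split(seq_len(nrow(mat)), mapping)
  rows <- lapply(groups, function(ii) {
    sub <- mat[ii, , drop = FALSE]
    if (is.infinite(top)) {
      apply(sub, 2, function(col) if (all(is.na(col))) NA_real_ else sum(col, na.rm = TRUE))
    } else {
      top_n_colsum(sub, top)
    }
  })
  out <- do.call(rbind, rows)
  dimnames(out) <- list(names(groups), colnames(mat))
  out
}

#' Run the full aggregation hierarchy
#'
#' @param peak_groups matrix of normalized peak-group intensities.
#' @param map data.frame (parallel to rows of `peak_groups`) with columns
#'   `glycopeptide`, `site_specific_glycan`, `protein_glycosite`.
#' @return list of matrices `glycopeptide`, `site_specific_glycan`,
#'   `protein_glycosite`.
#' @export
aggregate_hierarchy <- function(peak_groups, map) {
  gp <- aggregate_intensities(peak_groups, map$glycopeptide, top = 3L)
  ssg_map <- map$site_specific_glycan[match(rownames(gp), map$glycopeptide)]
  ssg <- aggregate_intensities(gp, ssg_map, top = 3L)
  site_map_tab <- unique(map[c("site_specific_glycan", "protein_glycosite")])
  site_map <- site_map_tab$protein_glycosite[
    match(rownames(ssg), site_map_tab$site_specific_glycan)]
  site <- aggregate_intensities(ssg, site_map, top = Inf)
  list(glycopeptide = gp, site_specific_glycan = ssg, protein_glycosite = site)
}

#' Coefficients of variation across technical replicates
#'
#' `CV = sd / mean` per analyte (sample standard deviation); analytes with
#' fewer than two non-missing replicate values get `NA`.
#'
#' @param mat intensity matrix (rows = analytes, columns = replicates).
#' @return list with `cv` (per-analyte vector) and `median_cv`.
#' @export
replicate_cv <- function(mat) {
  cv <- apply(mat, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) return(NA_real_)
    stats::sd(x) / mean(x)
  })
  list(cv = cv, median_cv = stats::median(cv, na.rm = TRUE))
}
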