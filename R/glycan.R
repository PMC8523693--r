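#' Glycan tree structures
#'
#' Glycans are rooted trees of monosaccharides written in canonical
#' parenthesis notation, e.g. `"(N(N(H(H)(H))))"` for the N-glycan
#' trimannosyl-chitobiose core. Each node is one monosaccharide; children
#' are ordered canonically (by serialized subtree) so that every tree has a
#' unique text form. These trees are the source of the theoretical Y-ion
#' fragment sets used for glycoform discrimination.
#'
#' @name glycan
NULL

.y_fragment_cache <- new.env(parent = emptyenv())

glycan_node <- function(code, children = list()) {
  list(code = code, children = children)
}

#' Parse a glycan structure string
#'
#' @param text canonical parenthesis string, e.g. `"(N(N(H(H)(H))))"`.
#' @param registry monosaccharide registry (see [monosaccharide_masses()]).
#' @return an object of class `glycan_struct`: a rooted tree with fields
#'   `code` and `children`, children in canonical order.
#' @export
parse_glycan <- function(text, registry = monosaccharide_masses()) {
  if (inherits(text, "glycan_struct")) return(text)
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(text)) stop("empty glycan string")
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  pos <- 0L
  n <- length(chars)
  peek <- function() if (pos < n) chars[pos + 1L] else NA_character_
  take <- function() {
    pos <<- pos + 1L
    if (pos > n) stop("malformed glycan string (unbalanced parentheses): ", text)
    chars[pos]
  }
  parse_node <- function() {
    if (!identical(take(), "(")) stop("malformed glycan string: expected '(' in ", text)
    code <- take()
    if (!code %in% names(registry))
      stop("unknown monosaccharide code '", code, "' in ", text)
    children <- list()
    while (identical(peek(), "(")) children[[length(children) + 1L]] <- parse_node()
    if (!identical(take(), ")")) stop("malformed glycan string (unbalanced parentheses): ", text)
    glycan_node(code, children)
  }
  root <- parse_node()
  if (pos != n) stop("malformed glycan string (trailing characters): ", text)
  root <- canonicalize_node(root)
  structure(root, class = "glycan_struct")
}

canonicalize_node <- function(node) {
  if (length(node$children)) {
    node$children <- lapply(node$children, canonicalize_node)
    node$children <- node$children[order(vapply(node$children, serialize_node, ""))]
  }
  node
}

serialize_node <- function(node) {
  paste0("(", node$code, paste0(vapply(node$children, serialize_node, ""), collapse = ""), ")")
}

#' Serialize a glycan tree to its canonical string
#' @param g a `glycan_struct`.
#' @return canonical parenthesis string.
#' @export
serialize_glycan <- function(g) serialize_node(g)

#' @export
print.glycan_struct <- function(x, ...) {
  cat("<glycan_struct> ", serialize_glycan(x), "\n", sep = "")
  invisible(x)
}

glycan_node_count <- function(node) {
  1L + sum(vapply(node$children, glycan_node_count, 0L))
}

#' Monosaccharide composition of a glycan
#'
#' @param g a `glycan_struct` or canonical string.
#' @param registry monosaccharide registry.
#' @return named integer vector of counts over the registry codes.
#' @export
glycan_composition <- function(g, registry = monosaccharide_masses()) {
  g <- parse_glycan(g, registry)
  counts <- stats::setNames(integer(length(registry)), names(registry))
  walk <- function(node) {
    counts[node$code] <<- counts[node$code] + 1L
    for (ch in node$children) walk(ch)
  }
  walk(g)
  counts
}

#' Composition key string
#'
#' Canonical text form of a monosaccharide composition: codes in
#' alphabetical order followed by their counts (zero counts omitted),
#' e.g. `"H3N2"`. The empty composition has the key `""`.
#'
#' @param counts named integer vector of monosaccharide counts.
#' @return single character key.
#' @export
composition_key <- function(counts) {
  counts <- counts[counts > 0]
  if (!length(counts)) return("")
  counts <- counts[order(names(counts))]
  paste0(names(counts), counts, collapse = "")
}

#' Parse a composition key back to counts
#' @param key composition key as produced by [composition_key()].
#' @param registry monosaccharide registry.
#' @return named integer vector over the registry codes.
#' @export
parse_composition_key <- function(key, registry = monosaccharide_masses()) {
  counts <- stats::setNames(integer(length(registry)), names(registry))
  if (!nzchar(key)) return(counts)
  m <- gregexpr("[A-Za-z][0-9]+", key)[[1]]
  parts <- regmatches(key, list(m))[[1]]
  if (!length(parts) || sum(attr(m, "match.length")) != nchar(key))
    stop("malformed composition key: ", key)
  for (p in parts) {
    code <- substr(p, 1L, 1L)
    if (!code %in% names(registry)) stop("unknown code in composition key: ", code)
    counts[code] <- counts[code] + as.integer(substr(p, 2L, nchar(p)))
  }
  counts
}

#' Mass of a glycan or composition
#'
#' @param x a `glycan_struct`, canonical string, composition key, or named
#'   count vector.
#' @param registry monosaccharide registry.
#' @return monoisotopic residue-mass sum in Da.
#' @export
glycan_mass <- function(x, registry = monosaccharide_masses()) {
  counts <- if (is.numeric(x)) {
    x
  } else if (inherits(x, "glycan_struct") || grepl("^\\(", x)) {
    glycan_composition(x, registry)
  } else {
    parse_composition_key(x, registry)
  }
  sum(counts * registry[names(counts)])
}

#' Enumerate theoretical Y fragments of a glycan
#'
#' A Y ion retains the intact peptide plus a root-containing connected
#' subtree of the glycan. Fragments are identified by monosaccharide
#' composition (Y ions of equal composition have equal m/z). The returned
#' set always contains the empty composition (Y0, the naked peptide) and
#' the full composition.
#'
#' @param g a `glycan_struct` or canonical string.
#' @param registry monosaccharide registry.
#' @return an object of class `y_fragment_set`: list with `keys` (character
#'   vector of composition keys, including `""`) and `full` (key of the
#'   intact glycan).
#' @export
enumerate_y_fragments <- function(g, registry = monosaccharide_masses()) {
  g <- parse_glycan(g, registry)
  cache_key <- paste(serialize_node(g), paste(names(registry), registry, collapse = ","))
  hit <- .y_fragment_cache[[cache_key]]
  if (!is.null(hit)) return(hit)
  codes <- names(registry)
  zero <- stats::setNames(integer(length(codes)), codes)
  # compositions of root-containing subtrees of the tree rooted at `node`
  rec <- function(node) {
    base <- zero
    base[node$code] <- 1L
    acc <- list(base)
    for (ch in node$children) {
      child_opts <- c(list(NULL), rec(ch))  # NULL = child pruned entirely
      acc <- unlist(lapply(acc, function(a) {
        lapply(child_opts, function(co) if (is.null(co)) a else a + co)
      }), recursive = FALSE)
      # dedupe by key to keep the cross product from growing redundantly
      keys <- vapply(acc, composition_key, "")
      acc <- acc[!duplicated(keys)]
    }
    acc
  }
  keys <- unique(c("", vapply(rec(g), composition_key, "")))
  out <- structure(list(keys = keys, full = composition_key(glycan_composition(g, registry))),
                   class = "y_fragment_set")
  .y_fragment_cache[[cache_key]] <- out
  out
}

#' @export
print.y_fragment_set <- function(x, ...) {
  cat("<y_fragment_set> ", length(x$keys), " fragments (full = ",
      x$full, ")\n", sep = "")
  invisible(x)
}

#' Jaccard similarity of two Y-fragment sets
#'
#' Ratio of shared theoretical Y fragments to their union. The empty
#' composition (Y0) is excluded from both sets: it is common to every
#' glycoform and carries no discriminating power for ranking.
#'
#' @param a,b `y_fragment_set` objects (or glycans, coerced).
#' @return similarity in `[0, 1]`.
#' @export
jaccard_similarity <- function(a, b) {
  if (!inherits(a, "y_fragment_set")) a <- enumerate_y_fragments(a)
  if (!inherits(b, "y_fragment_set")) b <- enumerate_y_fragments(b)
  ka <- setdiff(a$keys, "")
  kb <- setdiff(b$keys, "")
  if (!length(ka) || !length(kb)) stop("empty fragment set")
  length(intersect(ka, kb)) / length(union(ka, kb))
}

y_fragment_signature <- function(fs) paste(sort(fs$keys), collapse = ";")

#' Group isomeric glycan structures by fragment-set identity
#'
#' Isomeric structures (same monosaccharide composition) are combined when
#' their theoretical Y-fragment sets are exactly equal: such structures are
#' indistinguishable by Y-ion evidence.
#'
#' @param structs list (or character vector) of glycan structures sharing
#'   one composition.
#' @param registry monosaccharide registry.
#' @return list of groups; each group is a character vector of canonical
#'   structure strings.
#' @export
merge_isomers <- function(structs, registry = monosaccharide_masses()) {
  structs <- lapply(structs, parse_glycan, registry = registry)
  if (!length(structs)) return(list())
  comps <- vapply(structs, function(s) composition_key(glycan_composition(s, registry)), "")
  if (length(unique(comps)) > 1L)
    stop("merge_isomers requires structures sharing one composition")
  texts <- vapply(structs, serialize_glycan, "")
  sigs <- vapply(structs, function(s) y_fragment_signature(enumerate_y_fragments(s, registry)), "")
  keep <- !duplicated(texts)
  texts <- texts[keep]; sigs <- sigs[keep]
  grp <- split(texts, sigs)
  lapply(unname(grp), function(g) sort(g))
}
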