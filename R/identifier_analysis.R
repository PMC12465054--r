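# Identifier-level comparison of two maps: unique/shared symbol sets,
# per-diagram overlap matrices, cell-type protein profiles and their
# Jaccard similarity.

#' Unique canonical identifiers of a map
#'
#' The distinct canonical identifiers found anywhere in the map. By default
#' only HGNC symbols are counted — the stable comparison key for gene
#' products; widen with `namespaces` to include ChEBI ids and normalized
#' phenotype names.
#'
#' @param map A `disease_map`.
#' @param namespaces Character vector of namespaces to include
#'   (subset of `"HGNC"`, `"CHEBI"`, `"NAME"`).
#' @return Sorted character vector of canonical keys (e.g. `"HGNC:IL13"`).
#' @export
unique_identifiers <- function(map, namespaces = "HGNC") {
  ids <- canonical_ids(map)
  sort_c(unique(ids$key[ids$namespace %in% namespaces]))
}

#' Identifiers shared between two maps
#'
#' @param map_a,map_b `disease_map` objects.
#' @inheritParams unique_identifiers
#' @return Sorted character vector: the intersection of each map's
#'   [unique_identifiers()]. Symmetric in its arguments.
#' @export
shared_identifiers <- function(map_a, map_b, namespaces = "HGNC") {
  sort_c(intersect(unique_identifiers(map_a, namespaces),
                   unique_identifiers(map_b, namespaces)))
}

#' Disease-specific identifiers of each map
#'
#' @inheritParams shared_identifiers
#' @return A list with `only_a` and `only_b`, the set differences of each
#'   map's unique identifiers against the shared set.
#' @export
disease_specific_identifiers <- function(map_a, map_b, namespaces = "HGNC") {
  ua <- unique_identifiers(map_a, namespaces)
  ub <- unique_identifiers(map_b, namespaces)
  list(only_a = sort_c(setdiff(ua, ub)), only_b = sort_c(setdiff(ub, ua)))
}

# canonical keys per diagram, restricted to namespaces
diagram_key_sets <- function(map, namespaces) {
  ids <- canonical_ids(map)
  ids <- ids[ids$namespace %in% namespaces, , drop = FALSE]
  e <- map$elements
  dia <- e$diagram_id[match(ids$element_id, e$element_id)]
  sets <- split(ids$key, dia)
  out <- setNames(vector("list", nrow(map$diagrams)), map$diagrams$diagram_id)
  for (d in names(out)) out[[d]] <- sort_c(unique(sets[[d]] %||% character()))
  out
}

#' Per-diagram identifier overlap between two maps
#'
#' For every pair (diagram of map A, diagram of map B), the set of
#' canonical identifiers appearing in both. Pairs with fewer than
#' `min_overlap` shared identifiers are suppressed (default 3, so weak
#' coincidental overlaps drop out); `min_overlap = 0` reports all pairs.
#'
#' @inheritParams shared_identifiers
#' @param min_overlap Minimum shared-identifier count for a pair to be
#'   reported.
#' @return `data.frame` with columns `diagram_a`, `diagram_b`, `count` and
#'   `shared` (comma-joined keys), sorted by `count` descending, ties by
#'   diagram ids.
#' @export
diagram_overlap_matrix <- function(map_a, map_b, min_overlap = 3,
                                   namespaces = "HGNC") {
  sa <- diagram_key_sets(map_a, namespaces)
  sb <- diagram_key_sets(map_b, namespaces)
  rows <- list()
  for (da in names(sa)) {
    for (db in names(sb)) {
      shared <- intersect(sa[[da]], sb[[db]])
      if (length(shared) >= min_overlap) {
        rows[[length(rows) + 1L]] <- data.frame(
          diagram_a = da, diagram_b = db, count = length(shared),
          shared = paste(sort_c(shared), collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(diagram_a = character(), diagram_b = character(),
                      count = integer(), shared = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order_c(-out$count, out$diagram_a, out$diagram_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Symbol-by-diagram incidence table
#'
#' For a set of (typically shared) canonical identifiers, records in which
#' diagrams of either map each one appears, and ranks the symbols by total
#' diagram count so a "most frequently shared" listing can be read off the
#' top rows.
#'
#' @inheritParams shared_identifiers
#' @param symbols Character vector of canonical keys; normally a subset of
#'   [shared_identifiers()] — symbols outside that set trigger a warning.
#' @return A list with `incidence` (logical matrix, symbols x diagrams,
#'   diagram columns prefixed with the map id) and `ranking` (`data.frame`
#'   of `symbol`, `n_diagrams`, sorted descending, ties broken
#'   lexicographically).
#' @export
symbol_incidence <- function(map_a, map_b, symbols, namespaces = "HGNC") {
  symbols <- sort_c(unique(symbols))
  shared <- shared_identifiers(map_a, map_b, namespaces)
  stray <- setdiff(symbols, shared)
  if (length(stray)) {
    warning("symbol(s) not shared between the maps: ",
            paste(stray, collapse = ", "), call. = FALSE)
  }
  sa <- diagram_key_sets(map_a, namespaces)
  sb <- diagram_key_sets(map_b, namespaces)
  cols <- c(paste(map_a$map_id, names(sa), sep = ":"),
            paste(map_b$map_id, names(sb), sep = ":"))
  sets <- c(sa, sb)
  inc <- matrix(FALSE, nrow = length(symbols), ncol = length(cols),
                dimnames = list(symbols, cols))
  for (j in seq_along(sets)) inc[, j] <- symbols %in% sets[[j]]
  n_dia <- rowSums(inc)
  ranking <- data.frame(symbol = symbols, n_diagrams = as.integer(n_dia),
                        stringsAsFactors = FALSE)
  ranking <- ranking[order_c(-ranking$n_diagrams, ranking$symbol), , drop = FALSE]
  rownames(ranking) <- NULL
  list(incidence = inc, ranking = ranking)
}

#' Top shared symbols by diagram incidence
#'
#' Convenience wrapper ranking all shared identifiers of two maps by the
#' number of diagrams (across both maps) in which they appear.
#'
#' @inheritParams shared_identifiers
#' @param n Number of top symbols to return.
#' @return `data.frame` of `symbol`, `n_diagrams` (the top `n` rows of the
#'   [symbol_incidence()] ranking).
#' @export
top_shared_symbols <- function(map_a, map_b, n = 10, namespaces = "HGNC") {
  shared <- shared_identifiers(map_a, map_b, namespaces)
  if (length(shared) == 0) {
    return(data.frame(symbol = character(), n_diagrams = integer(),
                      stringsAsFactors = FALSE))
  }
  rk <- symbol_incidence(map_a, map_b, shared, namespaces)$ranking
  utils::head(rk, n)
}

#' Cell-type protein profiles
#'
#' One profile per distinct non-empty compartment (compartments carry the
#' cell-type name): the set of HGNC symbols of PROTEIN-class elements
#' assigned to that compartment, unioned over all diagrams. Elements with
#' an empty compartment contribute to no profile. `classes` widens the
#' selection to GENE/RNA elements if desired.
#'
#' @param map A `disease_map`.
#' @param classes Entity classes contributing to profiles.
#' @return Named list: cell type -> sorted character vector of HGNC keys.
#' @export
cell_type_profiles <- function(map, classes = "PROTEIN") {
  ids <- canonical_ids(map)
  ids <- ids[ids$namespace == "HGNC", , drop = FALSE]
  e <- map$elements
  keep <- match(ids$element_id, e$element_id)
  cls <- e$entity_class[keep]
  comp <- e$compartment[keep]
  sel <- cls %in% classes & nzchar(comp)
  profs <- lapply(split(ids$key[sel], comp[sel]), function(x) sort_c(unique(x)))
  profs[sort_c(names(profs))]
}

#' Jaccard index of two sets
#'
#' |A intersect B| / |A union B|; the empty-vs-empty case is defined as 0
#' (an empty compartment should not report self-similarity).
#'
#' @param a,b Character vectors (treated as sets).
#' @return A number in [0, 1].
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Cross-map cell-type Jaccard matrix
#'
#' Jaccard similarity of every (cell type in A, cell type in B) profile
#' pair. Values at or below `omit_threshold` are flagged `omitted`
#' (inclusive threshold, default 0.05) so near-zero coincidental overlap
#' can be suppressed in downstream tables and plots; the numeric value is
#' still reported.
#'
#' @param profiles_a,profiles_b Named lists from [cell_type_profiles()].
#' @param omit_threshold Values `<=` this are marked omitted.
#' @return `data.frame` with `cell_type_a`, `cell_type_b`, `value`,
#'   `omitted`.
#' @export
jaccard_matrix <- function(profiles_a, profiles_b, omit_threshold = 0.05) {
  rows <- expand.grid(cell_type_a = names(profiles_a) %||% character(),
                      cell_type_b = names(profiles_b) %||% character(),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- rows[order_c(rows$cell_type_a, rows$cell_type_b), , drop = FALSE]
  val <- mapply(function(ca, cb) jaccard_index(profiles_a[[ca]], profiles_b[[cb]]),
                rows$cell_type_a, rows$cell_type_b, USE.NAMES = FALSE)
  if (length(val) == 0) val <- numeric()
  rows$value <- val
  rows$omitted <- rows$value <= omit_threshold
  rownames(rows) <- NULL
  rows
}
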