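# Cross-map interaction matching: participant sets over canonical
# identifiers, Jaccard similarity, and the filtered match list
# (similarity >= 0.7 and at least two matching elements by default).

# small slack so a ratio that *is* the threshold (e.g. 7/10 vs 0.7)
# never fails on floating-point representation
EPS <- 1e-9

#' Comparison configuration
#'
#' All thresholds of the comparison pipeline in one validated record.
#'
#' @param min_similarity Minimum participant-set similarity for an
#'   interaction match (default 0.7).
#' @param min_shared_elements Minimum number of matching canonical
#'   identifiers for a match (default 2; a pair sharing a single element
#'   is rejected even at similarity 1).
#' @param min_similar_reactions Minimum number of matched interaction
#'   pairs for an SCC pair to form a similarity group (default 5).
#' @param role_strict If `TRUE`, only identifiers occupying the same role
#'   (source/target/modifier) on both sides count as matching.
#' @param include_modifiers If `FALSE`, modifiers are excluded from
#'   participant sets.
#' @param require_sign If `TRUE`, interactions only match when their signs
#'   agree.
#' @param omit_threshold Jaccard cells at or below this are marked omitted
#'   (default 0.05).
#' @param min_diagram_overlap Minimum per-diagram identifier overlap
#'   reported (default 3).
#' @param component_mode `"strong"` (strict SCCs, the default) or
#'   `"weak"` (weakly connected components, for feed-forward cascades
#'   without feedback).
#' @return A list of class `comparison_config`.
#' @export
comparison_config <- function(min_similarity = 0.7, min_shared_elements = 2,
                              min_similar_reactions = 5, role_strict = FALSE,
                              include_modifiers = TRUE, require_sign = FALSE,
                              omit_threshold = 0.05, min_diagram_overlap = 3,
                              component_mode = c("strong", "weak")) {
  component_mode <- match.arg(component_mode)
  stopifnot(is.numeric(min_similarity), min_similarity >= 0, min_similarity <= 1,
            min_shared_elements >= 0, min_similar_reactions >= 0,
            omit_threshold >= 0, min_diagram_overlap >= 0)
  structure(list(min_similarity = min_similarity,
                 min_shared_elements = as.integer(min_shared_elements),
                 min_similar_reactions = as.integer(min_similar_reactions),
                 role_strict = isTRUE(role_strict),
                 include_modifiers = isTRUE(include_modifiers),
                 require_sign = isTRUE(require_sign),
                 omit_threshold = omit_threshold,
                 min_diagram_overlap = as.integer(min_diagram_overlap),
                 component_mode = component_mode),
            class = "comparison_config")
}

# Per-interaction canonical-id sets, by role and as union.
# Returns a list keyed by interaction_id with fields sources, targets,
# modifiers, all (each a character vector of canonical keys);
# interactions with an empty union are flagged unmatchable.
participant_index <- function(map, include_modifiers = TRUE) {
  ids <- canonical_ids(map)
  key_of <- setNames(ids$key, ids$element_id)
  i <- map$interactions
  out <- vector("list", nrow(i))
  names(out) <- i$interaction_id
  for (k in seq_len(nrow(i))) {
    src <- unique(unname(key_of[i$sources[[k]]]))
    tgt <- unique(unname(key_of[i$targets[[k]]]))
    mod <- unique(unname(key_of[i$modifiers[[k]]]))
    src <- src[!is.na(src)]; tgt <- tgt[!is.na(tgt)]; mod <- mod[!is.na(mod)]
    all_ids <- unique(c(src, tgt, if (include_modifiers) mod))
    out[[k]] <- list(sources = src, targets = tgt, modifiers = mod,
                     all = all_ids, sign = i$sign[k],
                     unmatchable = length(all_ids) == 0)
  }
  out
}

#' Participant set of one interaction
#'
#' The deduplicated set of canonical identifiers over an interaction's
#' sources, targets and modifiers. Participants without a canonical
#' identifier are excluded; an interaction whose every participant lacks
#' one is flagged unmatchable and takes no part in matching.
#'
#' @param map A `disease_map`.
#' @param interaction_id Interaction identifier within `map`.
#' @param include_modifiers Include modifier elements (default `TRUE`).
#' @return A list with `interaction_id`, `ids` (character vector of
#'   canonical keys) and `unmatchable` (logical).
#' @export
participant_set <- function(map, interaction_id, include_modifiers = TRUE) {
  idx <- participant_index(map, include_modifiers)
  p <- idx[[interaction_id]]
  if (is.null(p)) stop("interaction not found in map: ", interaction_id)
  list(interaction_id = interaction_id, ids = sort_c(p$all),
       unmatchable = p$unmatchable)
}

#' Interaction participant-set similarity
#'
#' Jaccard index over the two participant sets of canonical identifiers,
#' the default similarity metric of the pipeline. Symmetric, in [0, 1].
#'
#' @param ids_a,ids_b Character vectors of canonical keys (non-empty).
#' @return A number in [0, 1].
#' @export
interaction_similarity <- function(ids_a, ids_b) {
  if (length(ids_a) == 0 || length(ids_b) == 0) {
    stop("interaction_similarity: empty participant set (should have been flagged unmatchable upstream)")
  }
  jaccard_index(ids_a, ids_b)
}

empty_match_df <- function() {
  data.frame(interaction_a = character(), interaction_b = character(),
             similarity = numeric(), matched = character(),
             n_matched = integer(), stringsAsFactors = FALSE)
}

#' Match interactions across two maps
#'
#' Scores every cross-map interaction pair by participant-set similarity
#' and keeps pairs meeting both thresholds: similarity at least
#' `cfg$min_similarity` and at least `cfg$min_shared_elements` matching
#' canonical identifiers. Candidate pairs are generated through an
#' inverted index on canonical identifiers, so only pairs sharing at least
#' one identifier are ever scored — no retained match can be missed
#' because any retained pair must share `min_shared_elements >= 1` ids.
#'
#' With `cfg$role_strict` the matched set is restricted to identifiers
#' occupying at least one common role (source/target/modifier) on both
#' sides; with `cfg$require_sign`, pairs with differing interaction signs
#' are discarded.
#'
#' @param map_a,map_b `disease_map` objects.
#' @param cfg A [comparison_config()].
#' @return `data.frame` with columns `interaction_a`, `interaction_b`,
#'   `similarity`, `matched` (comma-joined canonical keys), `n_matched`,
#'   ordered by similarity descending then interaction ids.
#' @export
match_interactions <- function(map_a, map_b, cfg = comparison_config()) {
  pa <- participant_index(map_a, cfg$include_modifiers)
  pb <- participant_index(map_b, cfg$include_modifiers)
  pa <- pa[!vapply(pa, `[[`, TRUE, "unmatchable")]
  pb <- pb[!vapply(pb, `[[`, TRUE, "unmatchable")]
  if (length(pa) == 0 || length(pb) == 0) return(empty_match_df())

  # inverted index: canonical key -> interactions of B containing it
  b_by_key <- list()
  for (ib in names(pb)) {
    for (k in pb[[ib]]$all) b_by_key[[k]] <- c(b_by_key[[k]], ib)
  }

  rows <- list()
  for (ia in names(pa)) {
    cand <- unique(unlist(b_by_key[pa[[ia]]$all], use.names = FALSE))
    for (ib in cand) {
      if (cfg$require_sign && !identical(pa[[ia]]$sign, pb[[ib]]$sign)) next
      shared <- intersect(pa[[ia]]$all, pb[[ib]]$all)
      matched <- if (cfg$role_strict) {
        role_shared <- c(intersect(pa[[ia]]$sources, pb[[ib]]$sources),
                         intersect(pa[[ia]]$targets, pb[[ib]]$targets),
                         intersect(pa[[ia]]$modifiers, pb[[ib]]$modifiers))
        unique(role_shared)
      } else {
        shared
      }
      if (length(matched) < cfg$min_shared_elements) next
      sim <- length(shared) / length(union(pa[[ia]]$all, pb[[ib]]$all))
      if (sim < cfg$min_similarity - EPS) next
      rows[[length(rows) + 1L]] <- data.frame(
        interaction_a = ia, interaction_b = ib, similarity = sim,
        matched = paste(sort_c(matched), collapse = ","),
        n_matched = length(matched), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty_match_df())
  out <- do.call(rbind, rows)
  out <- out[order_c(-out$similarity, out$interaction_a, out$interaction_b), ,
             drop = FALSE]
  rownames(out) <- NULL
  # contract check: every retained match satisfies both thresholds
  stopifnot(all(out$similarity >= cfg$min_similarity - EPS),
            all(out$n_matched >= cfg$min_shared_elements))
  out
}

#' Write an interaction match table as TSV
#'
#' @param matches Output of [match_interactions()].
#' @param map_a,map_b The maps the matches were computed on (used to
#'   annotate each side's diagram).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matches <- function(matches, map_a, map_b, path) {
  dia_a <- map_a$interactions$diagram_id[
    match(matches$interaction_a, map_a$interactions$interaction_id)]
  dia_b <- map_b$interactions$diagram_id[
    match(matches$interaction_b, map_b$interactions$interaction_id)]
  out <- data.frame(interaction_a = matches$interaction_a,
                    interaction_b = matches$interaction_b,
                    similarity = sprintf("%.4f", matches$similarity),
                    matched = matches$matched,
                    diagram_a = dia_a, diagram_b = dia_b,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
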