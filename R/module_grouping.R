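# Within-map reaction graphs, strongly connected components, cross-map
# similarity groups (SCC pairs linked by >= 5 matched interaction pairs)
# and disease-specific clusters.

#' Build a reaction-adjacency graph
#'
#' Nodes are interactions; a directed edge A -> B exists when some
#' canonical identifier among A's targets occurs among B's sources or
#' modifiers. Identity is canonical (HGNC/ChEBI/name), not element id, so
#' cascades that span diagrams of one map connect. Self-loops appear only
#' when an interaction's own targets feed its source/modifier set.
#'
#' @param map A `disease_map`.
#' @param restrict_to Interaction ids to include as nodes (default: all
#'   interactions of the map).
#' @return Object of class `reaction_graph`: list with `map_id`, `nodes`
#'   (character) and `edges` (`data.frame` of `from`, `to`).
#' @export
build_reaction_graph <- function(map, restrict_to = NULL) {
  all_ids <- map$interactions$interaction_id
  if (is.null(restrict_to)) restrict_to <- all_ids
  stray <- setdiff(restrict_to, all_ids)
  if (length(stray)) {
    stop("restrict_to contains unknown interaction id(s): ",
         paste(stray, collapse = ", "))
  }
  nodes <- sort_c(unique(restrict_to))
  idx <- participant_index(map)[nodes]
  # inverted index: canonical key -> nodes with it among sources/modifiers
  in_by_key <- list()
  for (id in nodes) {
    for (k in unique(c(idx[[id]]$sources, idx[[id]]$modifiers))) {
      in_by_key[[k]] <- c(in_by_key[[k]], id)
    }
  }
  from <- character(); to <- character()
  for (id in nodes) {
    succ <- unique(unlist(in_by_key[idx[[id]]$targets], use.names = FALSE))
    if (length(succ)) {
      from <- c(from, rep(id, length(succ)))
      to <- c(to, succ)
    }
  }
  edges <- data.frame(from = from, to = to, stringsAsFactors = FALSE)
  edges <- edges[order_c(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(map_id = map$map_id, nodes = nodes, edges = edges),
            class = "reaction_graph")
}

#' Connected components of a reaction graph
#'
#' Strongly connected components (mutual reachability, the default) or
#' weakly connected components of a [build_reaction_graph()] result.
#' Components partition the nodes; singletons are included. Member
#' ordering and component numbering are deterministic (components ordered
#' by their smallest member id).
#'
#' @param g A `reaction_graph`.
#' @param mode `"strong"` or `"weak"`.
#' @return List of components, each a list with `scc_id`, `map_id`,
#'   `members` (sorted character vector).
#' @export
strongly_connected_components <- function(g, mode = c("strong", "weak")) {
  mode <- match.arg(mode)
  if (length(g$nodes) == 0) return(list())
  ig <- igraph::graph_from_data_frame(g$edges, directed = TRUE,
                                      vertices = data.frame(name = g$nodes))
  memb <- igraph::components(ig, mode = mode)$membership
  comps <- split(names(memb), memb)
  comps <- lapply(comps, sort_c)
  comps <- comps[order_c(vapply(comps, `[[`, "", 1))]
  lapply(seq_along(comps), function(k) {
    list(scc_id = sprintf("%s_scc%04d", g$map_id, k), map_id = g$map_id,
         members = comps[[k]])
  })
}

#' Pair components across maps into similarity groups
#'
#' For every (component of A, component of B) pair, counts the distinct
#' matched interaction pairs with one endpoint in each; pairs reaching
#' `cfg$min_similar_reactions` (default 5) become similarity groups — the
#' unit of shared mechanism. A component may appear in several groups
#' (components are disjoint within a map but one may pair with several
#' opposite components).
#'
#' @param sccs_a,sccs_b Component lists from
#'   [strongly_connected_components()] for each map.
#' @param matches Match table from [match_interactions()].
#' @param cfg A [comparison_config()].
#' @return List of groups ordered by `n_similar` descending then component
#'   ids; each a list with `group_id`, `scc_a`, `scc_b`, `matches`
#'   (subset of the match table), `n_similar`.
#' @export
pair_components <- function(sccs_a, sccs_b, matches, cfg = comparison_config()) {
  if (nrow(matches) == 0 || length(sccs_a) == 0 || length(sccs_b) == 0) {
    return(list())
  }
  scc_of_a <- unlist(lapply(sccs_a, function(s) setNames(rep(s$scc_id, length(s$members)), s$members)))
  scc_of_b <- unlist(lapply(sccs_b, function(s) setNames(rep(s$scc_id, length(s$members)), s$members)))
  ka <- unname(scc_of_a[matches$interaction_a])
  kb <- unname(scc_of_b[matches$interaction_b])
  keep <- !is.na(ka) & !is.na(kb)
  if (!any(keep)) return(list())
  m <- matches[keep, , drop = FALSE]
  pair_key <- paste(ka[keep], kb[keep], sep = "\r")
  by_pair <- split(seq_len(nrow(m)), pair_key)
  counts <- vapply(by_pair, length, 0L)
  qual <- names(counts)[counts >= cfg$min_similar_reactions]
  if (length(qual) == 0) return(list())
  parts <- strsplit(qual, "\r", fixed = TRUE)
  ord <- order_c(-counts[qual],
                 vapply(parts, `[[`, "", 1), vapply(parts, `[[`, "", 2))
  qual <- qual[ord]
  a_by_id <- setNames(sccs_a, vapply(sccs_a, `[[`, "", "scc_id"))
  b_by_id <- setNames(sccs_b, vapply(sccs_b, `[[`, "", "scc_id"))
  lapply(seq_along(qual), function(k) {
    p <- strsplit(qual[k], "\r", fixed = TRUE)[[1]]
    sub <- m[by_pair[[qual[k]]], , drop = FALSE]
    rownames(sub) <- NULL
    list(group_id = sprintf("G%03d", k),
         scc_a = a_by_id[[p[1]]], scc_b = b_by_id[[p[2]]],
         matches = sub, n_similar = nrow(sub))
  })
}

#' Run the full grouping stage on two maps
#'
#' Convenience wrapper: matches interactions, builds each map's reaction
#' graph restricted to matched interactions, extracts components in
#' `cfg$component_mode`, and pairs them into similarity groups.
#'
#' @inheritParams match_interactions
#' @return A list with `matches`, `sccs_a`, `sccs_b`, `groups`,
#'   `component_mode`.
#' @export
similarity_groups <- function(map_a, map_b, cfg = comparison_config()) {
  matches <- match_interactions(map_a, map_b, cfg)
  ga <- build_reaction_graph(map_a, unique(matches$interaction_a))
  gb <- build_reaction_graph(map_b, unique(matches$interaction_b))
  sccs_a <- strongly_connected_components(ga, cfg$component_mode)
  sccs_b <- strongly_connected_components(gb, cfg$component_mode)
  groups <- pair_components(sccs_a, sccs_b, matches, cfg)
  list(matches = matches, sccs_a = sccs_a, sccs_b = sccs_b, groups = groups,
       component_mode = cfg$component_mode)
}

#' Interaction coverage of the similarity groups
#'
#' How many distinct interactions of each map fall inside any similarity
#' group (union of each group's component members), against each map's
#' total interaction count.
#'
#' @param groups Group list from [pair_components()].
#' @param map_a,map_b The compared maps.
#' @return A list with `n_covered_a`, `total_a`, `n_covered_b`, `total_b`.
#' @export
group_coverage <- function(groups, map_a, map_b) {
  cov_a <- unique(unlist(lapply(groups, function(g) g$scc_a$members)))
  cov_b <- unique(unlist(lapply(groups, function(g) g$scc_b$members)))
  list(n_covered_a = length(cov_a), total_a = nrow(map_a$interactions),
       n_covered_b = length(cov_b), total_b = nrow(map_b$interactions))
}

# canonical ids touched by a set of interactions of one map
interaction_key_sets <- function(map, interaction_ids) {
  idx <- participant_index(map)[interaction_ids]
  unique(unlist(lapply(idx, `[[`, "all"), use.names = FALSE))
}

#' Element frequency across similarity groups
#'
#' For each canonical identifier, the number of groups in which any member
#' interaction (on either map's side) involves it — highly recurrent hub
#' elements (e.g. core NF-kB machinery) surface at the top.
#'
#' @param groups Group list from [pair_components()].
#' @param map_a,map_b The compared maps.
#' @return `data.frame` of `key`, `n_groups`, ranked descending, ties
#'   broken lexicographically.
#' @export
element_group_frequency <- function(groups, map_a, map_b) {
  per_group <- lapply(groups, function(g) {
    unique(c(interaction_key_sets(map_a, g$scc_a$members),
             interaction_key_sets(map_b, g$scc_b$members)))
  })
  tab <- table(unlist(per_group, use.names = FALSE))
  if (length(tab) == 0) {
    return(data.frame(key = character(), n_groups = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(key = names(tab), n_groups = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order_c(-out$n_groups, out$key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Disease-specific interaction clusters
#'
#' Components of the reaction graph built only on interactions with no
#' cross-map match: the parts of one map's mechanism that are dissimilar
#' to every reaction of the other map.
#'
#' @param map The map to cluster.
#' @param matches Match table from [match_interactions()].
#' @param side `"a"` if `map` was the first argument to
#'   [match_interactions()], `"b"` otherwise.
#' @param mode Component mode (see [strongly_connected_components()]).
#' @return Component list sorted by size descending (ties by smallest
#'   member id).
#' @export
disease_specific_clusters <- function(map, matches, side = c("a", "b"),
                                      mode = c("strong", "weak")) {
  side <- match.arg(side)
  mode <- match.arg(mode)
  matched <- if (side == "a") matches$interaction_a else matches$interaction_b
  unmatched <- setdiff(map$interactions$interaction_id, matched)
  if (length(unmatched) == 0) return(list())
  g <- build_reaction_graph(map, unmatched)
  sccs <- strongly_connected_components(g, mode)
  sizes <- vapply(sccs, function(s) length(s$members), 0L)
  sccs[order_c(-sizes, vapply(sccs, function(s) s$members[1], ""))]
}

#' Write similarity groups as TSV and JSON
#'
#' TSV: one row per group (`group_id`, comma-joined members of each side,
#' `n_similar`). JSON: the full per-group match lists and matched
#' identifier sets, plus the component mode used.
#'
#' @param result Output of [similarity_groups()].
#' @param map_a,map_b The compared maps.
#' @param tsv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, a list of the written paths.
#' @export
write_groups <- function(result, map_a, map_b, tsv_path = NULL,
                         json_path = NULL) {
  groups <- result$groups
  if (!is.null(tsv_path)) {
    tab <- data.frame(
      group_id = vapply(groups, `[[`, "", "group_id"),
      scc_a = vapply(groups, function(g) g$scc_a$scc_id, ""),
      members_a = vapply(groups, function(g) paste(g$scc_a$members, collapse = ","), ""),
      scc_b = vapply(groups, function(g) g$scc_b$scc_id, ""),
      members_b = vapply(groups, function(g) paste(g$scc_b$members, collapse = ","), ""),
      n_similar = vapply(groups, function(g) g$n_similar, 0L),
      stringsAsFactors = FALSE)
    utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    doc <- list(component_mode = result$component_mode,
                n_groups = length(groups),
                groups = lapply(groups, function(g) {
                  list(group_id = g$group_id,
                       scc_a = g$scc_a$scc_id, members_a = g$scc_a$members,
                       scc_b = g$scc_b$scc_id, members_b = g$scc_b$members,
                       n_similar = g$n_similar,
                       matched_identifiers = sort_c(unique(unlist(
                         strsplit(g$matches$matched, ",", fixed = TRUE)))))
                }))
    txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = 2)
    con <- file(json_path, open = "wb")
    writeLines(txt, con = con, useBytes = TRUE)
    close(con)
  }
  invisible(list(tsv = tsv_path, json = json_path))
}
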