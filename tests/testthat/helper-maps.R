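# Compact builders for fixture maps, plus brute-force oracles used by the
# property and acceptance tests. Oracles are deliberately naive and share
# no code with the implementation they check.

el <- function(id, sym = NULL, class = "PROTEIN", dia = "d1", comp = "",
               name = if (!is.null(sym)) sym else id, ns = "HGNC") {
  ann <- if (is.null(sym)) {
    data.frame(namespace = character(), value = character(),
               stringsAsFactors = FALSE)
  } else {
    data.frame(namespace = ns, value = sym, stringsAsFactors = FALSE)
  }
  list(element_id = id, display_name = name, entity_class = class,
       diagram_id = dia, compartment = comp, annotations = ann)
}

ix <- function(id, src, tgt, mod = character(), dia = "d1",
               sign = "POSITIVE", refs = character()) {
  list(interaction_id = id, diagram_id = dia, sign = sign,
       sources = src, targets = tgt, modifiers = mod, references = refs)
}

mk_map <- function(map_id, els, ixs = list(), diagrams = NULL,
                   label = "test disease") {
  used <- unique(c(vapply(els, `[[`, "", "diagram_id"),
                   vapply(ixs, `[[`, "", "diagram_id")))
  if (is.null(diagrams)) {
    diagrams <- data.frame(diagram_id = used, name = used, kind = "PATHWAY",
                           cell_type = "", stringsAsFactors = FALSE)
  }
  elements <- data.frame(
    element_id = vapply(els, `[[`, "", "element_id"),
    display_name = vapply(els, `[[`, "", "display_name"),
    entity_class = vapply(els, `[[`, "", "entity_class"),
    diagram_id = vapply(els, `[[`, "", "diagram_id"),
    compartment = vapply(els, `[[`, "", "compartment"),
    stringsAsFactors = FALSE)
  elements$annotations <- I(lapply(els, `[[`, "annotations"))
  interactions <- data.frame(
    interaction_id = vapply(ixs, `[[`, "", "interaction_id"),
    diagram_id = vapply(ixs, `[[`, "", "diagram_id"),
    sign = vapply(ixs, `[[`, "", "sign"), stringsAsFactors = FALSE)
  if (length(ixs)) {
    interactions$sources <- I(lapply(ixs, `[[`, "sources"))
    interactions$targets <- I(lapply(ixs, `[[`, "targets"))
    interactions$modifiers <- I(lapply(ixs, `[[`, "modifiers"))
    interactions$references <- I(lapply(ixs, `[[`, "refs"))
  }
  disease_map(map_id, label, diagrams, elements, interactions)
}

# map holding one protein per symbol, one interaction per (src, tgt, mod)
# symbol triple; ids are derived from symbols
symbol_map <- function(map_id, edges, extra_syms = character()) {
  syms <- unique(c(unlist(lapply(edges, function(e) c(e$src, e$tgt, e$mod))),
                   extra_syms))
  els <- lapply(syms, function(s) el(paste0(map_id, "_", s), s))
  eid <- function(s) paste0(map_id, "_", s)
  ixs <- lapply(seq_along(edges), function(k) {
    e <- edges[[k]]
    ix(sprintf("%s_i%02d", map_id, k), vapply(e$src, eid, ""),
       vapply(e$tgt, eid, ""),
       if (is.null(e$mod)) character() else vapply(e$mod, eid, ""))
  })
  mk_map(map_id, els, ixs)
}

# ---- oracles ---------------------------------------------------------------

# element-by-element Jaccard: counts membership without set operations
jaccard_oracle <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- unique(c(a, b))
  if (length(u) == 0) return(0)
  n_both <- 0
  for (x in u) if (any(a == x) && any(b == x)) n_both <- n_both + 1
  n_both / length(u)
}

# SCC partition by mutual reachability over the transitive closure
# (Warshall on a boolean matrix); returns sets of node-name vectors
scc_oracle <- function(nodes, edges) {
  n <- length(nodes)
  reach <- diag(TRUE, n)
  dimnames(reach) <- list(nodes, nodes)
  for (k in seq_len(nrow(edges))) reach[edges$from[k], edges$to[k]] <- TRUE
  for (k in seq_len(n)) {
    reach <- reach | (outer(reach[, k], reach[k, ], `&`))
  }
  mutual <- reach & t(reach)
  comp_of <- rep(NA_integer_, n)
  cid <- 0L
  for (v in seq_len(n)) {
    if (is.na(comp_of[v])) {
      cid <- cid + 1L
      comp_of[which(mutual[v, ])] <- cid
    }
  }
  unname(lapply(split(nodes, comp_of), function(x) sort(x, method = "radix")))
}

# canonical form of a partition for comparison
partition_key <- function(sets) {
  sort(vapply(sets, paste, "", collapse = ","), method = "radix")
}

random_digraph <- function(n, p = 0.25) {
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  keep <- stats::runif(nrow(pairs)) < p
  list(nodes = nodes, edges = pairs[keep, , drop = FALSE])
}

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
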