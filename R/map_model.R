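# Data model for annotated molecular disease maps: diagrams, elements,
# signed directed interactions, plus the native JSON exchange format and
# an adapter for MINERVA project-export JSON.

#' @importFrom stats setNames
NULL

ELEMENT_CLASSES <- c("PROTEIN", "GENE", "RNA", "SIMPLE_MOLECULE",
                     "PHENOTYPE", "COMPLEX", "OTHER")
ANNOTATION_NAMESPACES <- c("HGNC", "UNIPROT", "CHEBI", "GO", "MESH")
INTERACTION_SIGNS <- c("POSITIVE", "NEGATIVE", "UNKNOWN")
DIAGRAM_KINDS <- c("INTERCELLULAR", "PATHWAY")
NATIVE_FORMAT_TAG <- "disease-map-json"
NATIVE_FORMAT_VERSION <- 1L

# locale-independent character sort (C collation) used everywhere results
# must be byte-stable
sort_c <- function(x) {
  if (length(x) == 0) return(character())
  sort(as.character(x), method = "radix")
}
order_c <- function(...) order(..., method = "radix")

as_chr <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x
}

# scalar variant: NULL / absent fields become ""
as_chr1 <- function(x) {
  x <- as_chr(x)
  if (length(x) == 0) "" else x[1]
}

#' Construct a disease map
#'
#' A disease map is a set of diagrams (an intercellular layer plus cell
#' type-specific pathway diagrams) holding annotated elements and signed
#' directed interactions. The constructor validates all structural
#' invariants: unique identifiers, known entity classes and signs,
#' non-empty source/target lists, and resolvable participant references.
#'
#' @param map_id Map identifier (e.g. a project id).
#' @param disease_label Human-readable disease name.
#' @param diagrams `data.frame` with columns `diagram_id`, `name`, `kind`
#'   (`"INTERCELLULAR"` or `"PATHWAY"`) and `cell_type` (may be `""`).
#' @param elements `data.frame` with columns `element_id`, `display_name`,
#'   `entity_class`, `diagram_id`, `compartment` and a list column
#'   `annotations`, each entry a `data.frame` with columns `namespace`
#'   and `value` (namespaces: HGNC, UNIPROT, CHEBI, GO, MESH).
#' @param interactions `data.frame` with columns `interaction_id`,
#'   `diagram_id`, `sign` and list columns `sources`, `targets`,
#'   `modifiers`, `references` (character vectors of element ids /
#'   PMID-DOI strings).
#' @return An object of class `disease_map`.
#' @examples
#' m <- disease_map("toy", "toy disease",
#'   diagrams = data.frame(diagram_id = "d1", name = "main",
#'                         kind = "INTERCELLULAR", cell_type = ""),
#'   elements = data.frame(element_id = c("e1", "e2"),
#'                         display_name = c("IL13", "IL13RA1"),
#'                         entity_class = "PROTEIN", diagram_id = "d1",
#'                         compartment = "",
#'                         annotations = I(list(
#'                           data.frame(namespace = "HGNC", value = "IL13"),
#'                           data.frame(namespace = "HGNC", value = "IL13RA1")))),
#'   interactions = data.frame(interaction_id = "i1", diagram_id = "d1",
#'                             sign = "POSITIVE",
#'                             sources = I(list("e1")), targets = I(list("e2")),
#'                             modifiers = I(list(character())),
#'                             references = I(list("PMID:1"))))
#' map_summary(m)
#' @export
disease_map <- function(map_id, disease_label = "", diagrams, elements,
                        interactions) {
  diagrams <- normalize_diagrams(diagrams)
  elements <- normalize_elements(elements)
  interactions <- normalize_interactions(interactions)
  m <- structure(
    list(map_id = as_chr(map_id)[1], disease_label = as_chr(disease_label)[1],
         diagrams = diagrams, elements = elements,
         interactions = interactions),
    class = "disease_map")
  validate_map(m)
  m
}

empty_annotations <- function(n) {
  I(replicate(n, data.frame(namespace = character(), value = character(),
                            stringsAsFactors = FALSE), simplify = FALSE))
}

normalize_diagrams <- function(d) {
  if (is.null(d) || nrow(d) == 0) {
    return(data.frame(diagram_id = character(), name = character(),
                      kind = character(), cell_type = character(),
                      stringsAsFactors = FALSE))
  }
  if (is.null(d$cell_type)) d$cell_type <- ""
  d <- data.frame(diagram_id = as_chr(d$diagram_id), name = as_chr(d$name),
                  kind = as_chr(d$kind), cell_type = as_chr(d$cell_type),
                  stringsAsFactors = FALSE)
  d <- d[order_c(d$diagram_id), , drop = FALSE]
  rownames(d) <- NULL
  d
}

normalize_annotation <- function(a) {
  if (is.null(a) || length(a) == 0) {
    return(data.frame(namespace = character(), value = character(),
                      stringsAsFactors = FALSE))
  }
  a <- data.frame(namespace = as_chr(a$namespace), value = as_chr(a$value),
                  stringsAsFactors = FALSE)
  # exact duplicate pairs collapse silently (annotations form a set);
  # order of first appearance is preserved so "first occurrence wins"
  # downstream is well defined
  a[!duplicated(paste(a$namespace, a$value, sep = "\r")), , drop = FALSE]
}

normalize_elements <- function(e) {
  if (is.null(e) || nrow(e) == 0) {
    return(data.frame(element_id = character(), display_name = character(),
                      entity_class = character(), diagram_id = character(),
                      compartment = character(),
                      annotations = empty_annotations(0),
                      stringsAsFactors = FALSE))
  }
  if (is.null(e$compartment)) e$compartment <- ""
  ann <- if (is.null(e$annotations)) {
    replicate(nrow(e), NULL, simplify = FALSE)
  } else {
    e$annotations
  }
  out <- data.frame(element_id = as_chr(e$element_id),
                    display_name = as_chr(e$display_name),
                    entity_class = as_chr(e$entity_class),
                    diagram_id = as_chr(e$diagram_id),
                    compartment = as_chr(e$compartment),
                    stringsAsFactors = FALSE)
  out$annotations <- I(lapply(ann, normalize_annotation))
  ord <- order_c(out$element_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

normalize_id_list <- function(x, n) {
  if (is.null(x)) x <- replicate(n, character(), simplify = FALSE)
  lapply(x, function(v) {
    v <- as_chr(unlist(v, use.names = FALSE))
    unique(v[nzchar(v)])
  })
}

normalize_interactions <- function(i) {
  if (is.null(i) || nrow(i) == 0) {
    return(data.frame(interaction_id = character(), diagram_id = character(),
                      sign = character(),
                      sources = I(list()), targets = I(list()),
                      modifiers = I(list()), references = I(list()),
                      stringsAsFactors = FALSE))
  }
  n <- nrow(i)
  out <- data.frame(interaction_id = as_chr(i$interaction_id),
                    diagram_id = as_chr(i$diagram_id),
                    sign = as_chr(i$sign), stringsAsFactors = FALSE)
  out$sign[out$sign == ""] <- "UNKNOWN"
  out$sources <- I(normalize_id_list(i$sources, n))
  out$targets <- I(normalize_id_list(i$targets, n))
  out$modifiers <- I(normalize_id_list(i$modifiers, n))
  out$references <- I(normalize_id_list(i$references, n))
  ord <- order_c(out$interaction_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Validate a disease map's structural invariants
#'
#' Checks identifier uniqueness, enum membership, annotation well-formedness,
#' non-empty interaction endpoints and that every participant and diagram
#' reference resolves. Called by [disease_map()]; exported so adapters and
#' callers can re-validate after manual edits.
#'
#' @param m A `disease_map`.
#' @return `m`, invisibly; stops with an informative error on violation.
#' @export
validate_map <- function(m) {
  stopifnot(inherits(m, "disease_map"))
  d <- m$diagrams; e <- m$elements; i <- m$interactions
  if (anyDuplicated(d$diagram_id)) {
    stop("duplicate diagram_id: ",
         paste(unique(d$diagram_id[duplicated(d$diagram_id)]), collapse = ", "))
  }
  bad_kind <- setdiff(unique(d$kind), DIAGRAM_KINDS)
  if (length(bad_kind)) stop("unknown diagram kind: ", paste(bad_kind, collapse = ", "))
  if (anyDuplicated(e$element_id)) {
    stop("duplicate element_id: ",
         paste(unique(e$element_id[duplicated(e$element_id)]), collapse = ", "))
  }
  bad_cls <- setdiff(unique(e$entity_class), ELEMENT_CLASSES)
  if (length(bad_cls)) stop("unknown entity_class: ", paste(bad_cls, collapse = ", "))
  bad_dia <- setdiff(unique(c(e$diagram_id, i$diagram_id)), d$diagram_id)
  if (length(bad_dia)) {
    stop("diagram_id not declared in diagrams: ", paste(bad_dia, collapse = ", "))
  }
  for (k in seq_len(nrow(e))) {
    a <- e$annotations[[k]]
    if (nrow(a) == 0) next
    if (any(!nzchar(a$namespace)) || any(!nzchar(a$value))) {
      stop("element ", e$element_id[k], ": annotation with empty namespace or value")
    }
    bad_ns <- setdiff(unique(a$namespace), ANNOTATION_NAMESPACES)
    if (length(bad_ns)) {
      stop("element ", e$element_id[k], ": unknown annotation namespace ",
           paste(bad_ns, collapse = ", "))
    }
  }
  if (anyDuplicated(i$interaction_id)) {
    stop("duplicate interaction_id: ",
         paste(unique(i$interaction_id[duplicated(i$interaction_id)]), collapse = ", "))
  }
  bad_sign <- setdiff(unique(i$sign), INTERACTION_SIGNS)
  if (length(bad_sign)) stop("unknown interaction sign: ", paste(bad_sign, collapse = ", "))
  known <- e$element_id
  for (k in seq_len(nrow(i))) {
    if (length(i$sources[[k]]) == 0 || length(i$targets[[k]]) == 0) {
      stop("interaction ", i$interaction_id[k], ": sources and targets must be non-empty")
    }
    parts <- c(i$sources[[k]], i$targets[[k]], i$modifiers[[k]])
    missing <- setdiff(parts, known)
    if (length(missing)) {
      stop("interaction ", i$interaction_id[k],
           ": participant element_id not found in map: ",
           paste(missing, collapse = ", "))
    }
  }
  invisible(m)
}

#' @export
print.disease_map <- function(x, ...) {
  cat(sprintf("<disease_map> %s (%s)\n", x$map_id, x$disease_label))
  cat(sprintf("  %d diagrams, %d elements, %d interactions\n",
              nrow(x$diagrams), nrow(x$elements), nrow(x$interactions)))
  invisible(x)
}

## ---- canonical identifiers ------------------------------------------------

#' Canonical comparison identifiers for all elements of a map
#'
#' The per-element comparison key used throughout the cross-map analyses:
#' gene products (PROTEIN/GENE/RNA) map to their uppercased HGNC symbol,
#' simple molecules to their ChEBI id, phenotypes to a lowercased,
#' whitespace-collapsed display name. Elements with no applicable rule
#' (complexes, unannotated proteins, GO/MeSH-only entries) carry no
#' canonical identifier and are excluded from identifier analyses.
#'
#' When an element carries several annotations in one namespace the first
#' occurrence wins and a warning is emitted once per map.
#'
#' @param map A `disease_map`.
#' @return `data.frame` with one row per canonicalizable element:
#'   `element_id`, `namespace` (HGNC/CHEBI/NAME), `value`, and `key`, the
#'   namespace-qualified string used as set member in all comparisons.
#' @export
canonical_ids <- function(map) {
  e <- map$elements
  n <- nrow(e)
  ns <- character(n); val <- character(n)
  dup_warned <- FALSE
  for (k in seq_len(n)) {
    cls <- e$entity_class[k]
    a <- e$annotations[[k]]
    if (cls %in% c("PROTEIN", "GENE", "RNA")) {
      hits <- which(a$namespace == "HGNC")
      if (length(hits) >= 1) {
        if (length(hits) > 1 && !dup_warned) {
          warning("element(s) with multiple HGNC annotations; first occurrence wins",
                  call. = FALSE)
          dup_warned <- TRUE
        }
        ns[k] <- "HGNC"
        val[k] <- toupper(a$value[hits[1]])
      }
    } else if (cls == "SIMPLE_MOLECULE") {
      hits <- which(a$namespace == "CHEBI")
      if (length(hits) >= 1) {
        ns[k] <- "CHEBI"
        v <- toupper(a$value[hits[1]])
        if (!startsWith(v, "CHEBI:")) v <- paste0("CHEBI:", v)
        val[k] <- v
      }
    } else if (cls == "PHENOTYPE") {
      nm <- tolower(trimws(gsub("\\s+", " ", e$display_name[k])))
      if (nzchar(nm)) {
        ns[k] <- "NAME"
        val[k] <- nm
      }
    }
  }
  keep <- nzchar(ns)
  ns_k <- ns[keep]; val_k <- val[keep]
  key <- paste(ns_k, val_k, sep = ":")
  key[ns_k == "CHEBI"] <- val_k[ns_k == "CHEBI"]  # value already prefixed
  data.frame(element_id = e$element_id[keep], namespace = ns_k,
             value = val_k, key = key, stringsAsFactors = FALSE)
}

#' Canonical identifier of a single element
#'
#' @param map A `disease_map`.
#' @param element_id Element identifier within `map`.
#' @return A list with `namespace`, `value` and `key`, or `NULL` if the
#'   element has no canonical identifier.
#' @export
canonical_identifier <- function(map, element_id) {
  ids <- canonical_ids(map)
  hit <- ids[ids$element_id == element_id, , drop = FALSE]
  if (nrow(hit) == 0) return(NULL)
  list(namespace = hit$namespace[1], value = hit$value[1], key = hit$key[1])
}

## ---- summary --------------------------------------------------------------

#' Summarize a disease map
#'
#' Parse-level content statistics: element and interaction counts, the
#' number of distinct molecular entities (distinct canonical identifiers
#' over PROTEIN, GENE, RNA and SIMPLE_MOLECULE elements — the same
#' protein drawn in several diagrams counts once), diagram count and the
#' number of distinct literature references.
#'
#' @param map A `disease_map`.
#' @return A list with `n_elements`, `n_interactions`,
#'   `n_unique_molecular_entities`, `n_diagrams`, `n_references`.
#' @export
map_summary <- function(map) {
  ids <- canonical_ids(map)
  mol_cls <- c("PROTEIN", "GENE", "RNA", "SIMPLE_MOLECULE")
  mol_elems <- map$elements$element_id[map$elements$entity_class %in% mol_cls]
  mol_keys <- unique(ids$key[ids$element_id %in% mol_elems])
  refs <- unique(unlist(map$interactions$references, use.names = FALSE))
  list(n_elements = nrow(map$elements),
       n_interactions = nrow(map$interactions),
       n_unique_molecular_entities = length(mol_keys),
       n_diagrams = nrow(map$diagrams),
       n_references = length(refs))
}

#' @export
summary.disease_map <- function(object, ...) map_summary(object)

## ---- native JSON format ---------------------------------------------------

#' Write a disease map to the native JSON exchange format
#'
#' Versioned UTF-8 JSON mirroring the in-memory model field for field.
#' Records are emitted in canonical (C-collation) id order so output is
#' byte-stable: the same map always serializes to the same bytes, and
#' `load_map(write_map(m))` reproduces `m` exactly.
#'
#' @param map A `disease_map`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  validate_map(map)
  e <- map$elements
  i <- map$interactions
  doc <- list(
    format = NATIVE_FORMAT_TAG,
    version = NATIVE_FORMAT_VERSION,
    map_id = map$map_id,
    disease_label = map$disease_label,
    diagrams = lapply(seq_len(nrow(map$diagrams)), function(k) {
      as.list(map$diagrams[k, c("diagram_id", "name", "kind", "cell_type")])
    }),
    elements = lapply(seq_len(nrow(e)), function(k) {
      a <- e$annotations[[k]]
      list(element_id = e$element_id[k], display_name = e$display_name[k],
           entity_class = e$entity_class[k], diagram_id = e$diagram_id[k],
           compartment = e$compartment[k],
           annotations = lapply(seq_len(nrow(a)),
                                function(j) list(a$namespace[j], a$value[j])))
    }),
    interactions = lapply(seq_len(nrow(i)), function(k) {
      list(interaction_id = i$interaction_id[k], diagram_id = i$diagram_id[k],
           sign = i$sign[k],
           sources = as.list(i$sources[[k]]), targets = as.list(i$targets[[k]]),
           modifiers = as.list(i$modifiers[[k]]),
           references = as.list(i$references[[k]]))
    }))
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = 2, null = "null")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(txt, con = con, useBytes = TRUE)
  invisible(path)
}

#' Load a disease map
#'
#' Reads either the native JSON exchange format written by [write_map()] or
#' the JSON structure of a MINERVA project export (see
#' [read_minerva_export()] for the field mapping). The returned map is
#' fully validated; a load report (counts of parsed and dropped records)
#' is attached as attribute `"load_report"`.
#'
#' @param path Path to the map file.
#' @param format `"NATIVE"` or `"MINERVA_EXPORT"`.
#' @return A validated `disease_map`.
#' @export
load_map <- function(path, format = c("NATIVE", "MINERVA_EXPORT")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("map file not found: ", path)
  if (format == "MINERVA_EXPORT") return(read_minerva_export(path))
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$format, NATIVE_FORMAT_TAG)) {
    stop("not a ", NATIVE_FORMAT_TAG, " file: ", path)
  }
  if (!identical(as.integer(doc$version), NATIVE_FORMAT_VERSION)) {
    stop("unsupported native format version: ", doc$version)
  }
  diagrams <- do.call(rbind, lapply(doc$diagrams, function(d) {
    data.frame(diagram_id = as_chr(d$diagram_id), name = as_chr(d$name),
               kind = as_chr(d$kind), cell_type = as_chr(d$cell_type),
               stringsAsFactors = FALSE)
  }))
  elements <- data.frame(
    element_id = vapply(doc$elements, function(x) as_chr(x$element_id), ""),
    display_name = vapply(doc$elements, function(x) as_chr(x$display_name), ""),
    entity_class = vapply(doc$elements, function(x) as_chr(x$entity_class), ""),
    diagram_id = vapply(doc$elements, function(x) as_chr(x$diagram_id), ""),
    compartment = vapply(doc$elements, function(x) as_chr(x$compartment), ""),
    stringsAsFactors = FALSE)
  elements$annotations <- I(lapply(doc$elements, function(x) {
    if (length(x$annotations) == 0) {
      return(data.frame(namespace = character(), value = character(),
                        stringsAsFactors = FALSE))
    }
    data.frame(namespace = vapply(x$annotations, function(p) as_chr(p[[1]]), ""),
               value = vapply(x$annotations, function(p) as_chr(p[[2]]), ""),
               stringsAsFactors = FALSE)
  }))
  interactions <- data.frame(
    interaction_id = vapply(doc$interactions, function(x) as_chr(x$interaction_id), ""),
    diagram_id = vapply(doc$interactions, function(x) as_chr(x$diagram_id), ""),
    sign = vapply(doc$interactions, function(x) as_chr(x$sign), ""),
    stringsAsFactors = FALSE)
  pull_list <- function(field) {
    I(lapply(doc$interactions,
             function(x) as_chr(unlist(x[[field]], use.names = FALSE))))
  }
  interactions$sources <- pull_list("sources")
  interactions$targets <- pull_list("targets")
  interactions$modifiers <- pull_list("modifiers")
  interactions$references <- pull_list("references")
  m <- disease_map(doc$map_id, doc$disease_label, diagrams, elements, interactions)
  attr(m, "load_report") <- list(format = "NATIVE",
                                 n_elements = nrow(m$elements),
                                 n_interactions = nrow(m$interactions),
                                 n_dropped_elements = 0L,
                                 n_dropped_interactions = 0L)
  m
}

## ---- MINERVA export adapter -----------------------------------------------

# Field mapping, MINERVA project export -> disease_map:
#   models[].idObject        -> diagram_id
#   models[].name            -> name; kind INTERCELLULAR when the name
#                               contains "intercellular" or "main",
#                               else PATHWAY with cell_type = name
#   elements[].id            -> element_id
#   elements[].name          -> display_name
#   elements[].type          -> entity_class (Protein/Gene/Rna/
#                               Simple molecule/Phenotype/Complex -> enum)
#   elements[].model         -> diagram_id
#   elements[].compartmentName -> compartment
#   elements[].references[]  -> annotations; reference type HGNC_SYMBOL ->
#                               HGNC, UNIPROT -> UNIPROT, CHEBI -> CHEBI,
#                               GO -> GO, MESH_2012/MESH -> MESH
#   reactions[].id           -> interaction_id
#   reactions[].model        -> diagram_id
#   reactions[].type         -> sign (inhibition/negative -> NEGATIVE,
#                               activation/stimulation/positive -> POSITIVE,
#                               else UNKNOWN)
#   reactions[].reactants[].element -> sources
#   reactions[].products[].element  -> targets
#   reactions[].modifiers[].element -> modifiers
#   reactions[].references[].resource -> references

minerva_entity_class <- function(type) {
  t <- toupper(gsub("[ _]", "", as_chr(type)))
  switch(t,
         PROTEIN = "PROTEIN", GENE = "GENE", RNA = "RNA",
         SIMPLEMOLECULE = "SIMPLE_MOLECULE", PHENOTYPE = "PHENOTYPE",
         COMPLEX = "COMPLEX", "OTHER")
}

minerva_sign <- function(type) {
  t <- tolower(as_chr(type))
  if (grepl("inhibition|negative", t)) return("NEGATIVE")
  if (grepl("activation|stimulation|positive|catalysis|trigger", t)) return("POSITIVE")
  "UNKNOWN"
}

minerva_namespace <- function(type) {
  t <- toupper(as_chr(type))
  if (t %in% c("HGNC_SYMBOL", "HGNC")) return("HGNC")
  if (t == "UNIPROT") return("UNIPROT")
  if (t == "CHEBI") return("CHEBI")
  if (startsWith(t, "GO")) return("GO")
  if (startsWith(t, "MESH")) return("MESH")
  NA_character_
}

minerva_participant <- function(p) {
  # participants appear either as {"element": id}, {"id": id} or bare ids
  if (is.list(p)) {
    v <- p[["element"]]
    if (is.null(v)) v <- p[["id"]]
    if (is.list(v)) v <- v[["id"]]
    as_chr(v)
  } else {
    as_chr(p)
  }
}

#' Read a MINERVA project export as a disease map
#'
#' Adapter for the JSON structure returned by a MINERVA "project export":
#' `models` become diagrams, `elements` (with their `references` lists)
#' become annotated elements, `reactions` (with reactants / products /
#' modifiers) become signed interactions. The field-by-field mapping is
#' documented in the package source and the methods vignette.
#' Records that cannot be interpreted (e.g. reactions without reactants or
#' products) are dropped with a warning and counted in the load report
#' attached as attribute `"load_report"`.
#'
#' @param path Path to a MINERVA project-export JSON file.
#' @return A validated `disease_map`.
#' @export
read_minerva_export <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$models) || is.null(doc$elements)) {
    stop("not a MINERVA project export (missing 'models'/'elements'): ", path)
  }
  diagrams <- do.call(rbind, lapply(doc$models, function(mdl) {
    nm <- as_chr1(mdl$name)
    inter <- grepl("intercellular|main", tolower(nm))
    data.frame(diagram_id = as_chr1(mdl$idObject), name = nm,
               kind = if (inter) "INTERCELLULAR" else "PATHWAY",
               cell_type = if (inter) "" else nm, stringsAsFactors = FALSE)
  }))
  n_drop_e <- 0L
  el_rows <- list()
  for (x in doc$elements) {
    if (is.null(x$id) || is.null(x$model)) {
      n_drop_e <- n_drop_e + 1L
      next
    }
    anns <- list(namespace = character(), value = character())
    for (r in x$references) {
      ns <- minerva_namespace(r$type)
      if (is.na(ns)) next
      anns$namespace <- c(anns$namespace, ns)
      anns$value <- c(anns$value, as_chr1(r$resource))
    }
    el_rows[[length(el_rows) + 1L]] <- list(
      element_id = as_chr1(x$id), display_name = as_chr1(x$name),
      entity_class = minerva_entity_class(x$type),
      diagram_id = as_chr1(x$model),
      compartment = as_chr1(x$compartmentName),
      annotations = data.frame(namespace = anns$namespace, value = anns$value,
                               stringsAsFactors = FALSE))
  }
  elements <- data.frame(
    element_id = vapply(el_rows, `[[`, "", "element_id"),
    display_name = vapply(el_rows, `[[`, "", "display_name"),
    entity_class = vapply(el_rows, `[[`, "", "entity_class"),
    diagram_id = vapply(el_rows, `[[`, "", "diagram_id"),
    compartment = vapply(el_rows, `[[`, "", "compartment"),
    stringsAsFactors = FALSE)
  elements$annotations <- I(lapply(el_rows, `[[`, "annotations"))

  n_drop_i <- 0L
  in_rows <- list()
  for (x in doc$reactions) {
    src <- unique(vapply(x$reactants, minerva_participant, ""))
    tgt <- unique(vapply(x$products, minerva_participant, ""))
    mod <- unique(vapply(x$modifiers, minerva_participant, ""))
    if (is.null(x$id) || length(src) == 0 || length(tgt) == 0) {
      n_drop_i <- n_drop_i + 1L
      next
    }
    refs <- vapply(x$references, function(r) as_chr1(r$resource), "")
    in_rows[[length(in_rows) + 1L]] <- list(
      interaction_id = as_chr1(x$id), diagram_id = as_chr1(x$model),
      sign = minerva_sign(x$type), sources = src, targets = tgt,
      modifiers = mod, references = refs[nzchar(refs)])
  }
  interactions <- data.frame(
    interaction_id = vapply(in_rows, `[[`, "", "interaction_id"),
    diagram_id = vapply(in_rows, `[[`, "", "diagram_id"),
    sign = vapply(in_rows, `[[`, "", "sign"), stringsAsFactors = FALSE)
  interactions$sources <- I(lapply(in_rows, `[[`, "sources"))
  interactions$targets <- I(lapply(in_rows, `[[`, "targets"))
  interactions$modifiers <- I(lapply(in_rows, `[[`, "modifiers"))
  interactions$references <- I(lapply(in_rows, `[[`, "references"))

  if (n_drop_e + n_drop_i > 0) {
    warning(sprintf("MINERVA export %s: dropped %d element(s), %d reaction(s) that could not be parsed",
                    path, n_drop_e, n_drop_i), call. = FALSE)
  }
  m <- disease_map(as_chr1(doc$projectId %||% basename(path)),
                   as_chr1(doc$name %||% ""), diagrams, elements, interactions)
  attr(m, "load_report") <- list(format = "MINERVA_EXPORT",
                                 n_elements = nrow(m$elements),
                                 n_interactions = nrow(m$interactions),
                                 n_dropped_elements = n_drop_e,
                                 n_dropped_interactions = n_drop_i)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
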