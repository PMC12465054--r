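test_that("native format round-trips field-for-field and is byte-stable", {
  m <- mk_map("rt",
    els = list(el("e1", "IL13"), el("e2", "JAK1", comp = "Th2 cell"),
               el("e3", "16412", class = "SIMPLE_MOLECULE", ns = "CHEBI"),
               el("e4", class = "PHENOTYPE", name = "Chronic   Itch ü")),
    ixs = list(ix("i1", "e1", "e2", mod = "e3", refs = c("PMID:1", "DOI:x")),
               ix("i2", c("e2", "e3"), "e4", sign = "NEGATIVE")))
  f1 <- tempfile(); f2 <- tempfile()
  write_map(m, f1)
  write_map(m, f2)
  expect_identical(readBin(f1, "raw", file.size(f1) + 10),
                   readBin(f2, "raw", file.size(f2) + 10))
  m2 <- load_map(f1)
  attr(m2, "load_report") <- NULL
  expect_equal(unclass(m2), unclass(m))
  # unicode display names survive verbatim
  expect_true("Chronic   Itch ü" %in% m2$elements$display_name)
})

test_that("round trip reproduces a 50-element synthetic map", {
  pair <- generate_map_pair(sim_config(seed = 11, n_cell_types_per_map = 2,
                                       n_shared_cell_types = 1,
                                       proteins_per_cell_type = 20,
                                       n_planted_modules = 1,
                                       n_background_interactions = 5))
  expect_gte(nrow(pair$map_a$elements), 50)
  f <- tempfile()
  write_map(pair$map_a, f)
  m2 <- load_map(f)
  attr(m2, "load_report") <- NULL
  expect_equal(unclass(m2), unclass(pair$map_a))
})

test_that("validation rejects structural violations and names the offender", {
  base_els <- list(el("e1", "IL13"), el("e2", "JAK1"))
  expect_error(mk_map("m", base_els, list(ix("i1", "e1", "ghost42"))),
               "ghost42")
  expect_error(mk_map("m", base_els, list(ix("i1", "e1", character()))),
               "non-empty")
  expect_error(mk_map("m", list(el("e1", "IL13"), el("e1", "JAK1"))),
               "duplicate element_id")
  expect_error(mk_map("m", list(el("e1", "IL13", class = "WIDGET"))),
               "entity_class")
  bad_ann <- list(el("e1", "IL13", ns = "FOO"))
  expect_error(mk_map("m", bad_ann), "namespace")
})

test_that("a dangling participant in a native file is fatal and names the id", {
  m <- mk_map("m", list(el("e1", "IL13"), el("e2", "JAK1")),
              list(ix("i1", "e1", "e2")))
  f <- tempfile()
  write_map(m, f)
  doc <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  doc$interactions[[1]]$targets <- list("nowhere9")
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE), f)
  expect_error(load_map(f), "nowhere9")
})

test_that("canonical identifier rules follow entity class and namespace", {
  m <- mk_map("c", list(
    el("p1", "il13"),                                   # lowercase HGNC
    el("g1", "NOD2", class = "GENE"),
    el("r1", "MIR21", class = "RNA"),
    el("s1", "16412", class = "SIMPLE_MOLECULE", ns = "CHEBI"),
    el("s2", "CHEBI:29108", class = "SIMPLE_MOLECULE", ns = "CHEBI"),
    el("ph", class = "PHENOTYPE", name = "  Barrier   Disruption "),
    el("p2", class = "PROTEIN", name = "unannotated"),  # no HGNC -> none
    el("cx", "IL13", class = "COMPLEX"),                # complexes excluded
    el("p3", "STAT6", class = "PROTEIN", ns = "UNIPROT")))
  ids <- canonical_ids(m)
  get <- function(id) ids[ids$element_id == id, ]
  expect_equal(get("p1")$key, "HGNC:IL13")
  expect_equal(get("g1")$key, "HGNC:NOD2")
  expect_equal(get("r1")$key, "HGNC:MIR21")
  expect_equal(get("s1")$key, "CHEBI:16412")
  expect_equal(get("s2")$key, "CHEBI:29108")
  expect_equal(get("ph")$namespace, "NAME")
  expect_equal(get("ph")$value, "barrier disruption")
  expect_false(any(c("p2", "cx", "p3") %in% ids$element_id))
  expect_null(canonical_identifier(m, "p2"))
  expect_equal(canonical_identifier(m, "p1")$key, "HGNC:IL13")
})

test_that("duplicate in-namespace annotations: first occurrence wins, with warning", {
  e <- el("e1", "IL13")
  e$annotations <- data.frame(namespace = c("HGNC", "HGNC"),
                              value = c("IL13", "IL13RA1"),
                              stringsAsFactors = FALSE)
  m <- mk_map("m", list(e))
  expect_warning(ids <- canonical_ids(m), "first occurrence")
  expect_equal(ids$key, "HGNC:IL13")
})

test_that("summary counts: empty map, dedup across diagrams", {
  empty <- mk_map("z", list(el("e0", "X1")), list())
  empty$elements <- empty$elements[0, ]
  empty$interactions <- empty$interactions[0, ]
  empty$diagrams <- empty$diagrams[0, ]
  s <- map_summary(empty)
  expect_equal(unlist(s), c(n_elements = 0, n_interactions = 0,
                            n_unique_molecular_entities = 0, n_diagrams = 0,
                            n_references = 0))
  # same protein drawn in three diagrams counts once as molecular entity
  m3 <- mk_map("m3", list(el("a", "IL13", dia = "d1"),
                          el("b", "IL13", dia = "d2"),
                          el("c", "IL13", dia = "d3")))
  s3 <- map_summary(m3)
  expect_equal(s3$n_elements, 3)
  expect_equal(s3$n_unique_molecular_entities, 1)
  expect_equal(s3$n_diagrams, 3)
  # invariant: unique entities never exceed elements
  expect_lte(s3$n_unique_molecular_entities, s3$n_elements)
})

test_that("MINERVA export adapter maps models/elements/reactions", {
  doc <- list(
    projectId = "TESTmap01",
    name = "test disease",
    models = list(
      list(idObject = 101, name = "Intercellular overview"),
      list(idObject = 102, name = "Th1 cell")),
    elements = list(
      list(id = 1, name = "IL18", type = "Protein", model = 101,
           compartmentName = "Th1 cell",
           references = list(list(type = "HGNC_SYMBOL", resource = "IL18"),
                             list(type = "UNIPROT", resource = "Q14116"))),
      list(id = 2, name = "IL18R1", type = "Protein", model = 101,
           references = list(list(type = "HGNC_SYMBOL", resource = "IL18R1"))),
      list(id = 3, name = "ATP", type = "Simple molecule", model = 102,
           references = list(list(type = "CHEBI", resource = "CHEBI:15422"))),
      list(id = 4, name = "inflammation", type = "Phenotype", model = 102,
           references = list(list(type = "MESH_2012", resource = "D007249")))),
    reactions = list(
      list(id = 11, model = 101, type = "Positive influence",
           reactants = list(list(element = 1)),
           products = list(list(element = 2)),
           modifiers = list(),
           references = list(list(resource = "PMID:123"))),
      list(id = 12, model = 102, type = "Negative influence",
           reactants = list(list(element = 3)),
           products = list(list(element = 4)),
           modifiers = list(list(element = 2)),
           references = list()),
      list(id = 13, model = 102, type = "State transition",
           reactants = list(), products = list(list(element = 4)),
           modifiers = list(), references = list())))
  f <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE), f)
  expect_warning(m <- load_map(f, "MINERVA_EXPORT"), "dropped")
  rep <- attr(m, "load_report")
  expect_equal(rep$n_dropped_interactions, 1) # reaction 13 has no reactants
  expect_equal(nrow(m$elements), 4)
  expect_equal(nrow(m$interactions), 2)
  expect_equal(m$map_id, "TESTmap01")
  expect_setequal(m$diagrams$kind, c("INTERCELLULAR", "PATHWAY"))
  expect_equal(m$diagrams$cell_type[m$diagrams$kind == "PATHWAY"], "Th1 cell")
  i <- m$interactions
  expect_equal(i$sign[i$interaction_id == "11"], "POSITIVE")
  expect_equal(i$sign[i$interaction_id == "12"], "NEGATIVE")
  expect_equal(i$modifiers[i$interaction_id == "12"][[1]], "2")
  ids <- canonical_ids(m)
  expect_setequal(ids$key[ids$namespace == "HGNC"], c("HGNC:IL18", "HGNC:IL18R1"))
  expect_true("CHEBI:15422" %in% ids$key)
})

test_that("load_map errors on missing files and wrong schema", {
  expect_error(load_map(tempfile()), "not found")
  f <- tempfile()
  writeLines('{"foo": 1}', f)
  expect_error(load_map(f), "disease-map-json")
})
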