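# chain A->B->C over symbols: g1 -i1-> g2 -i2-> g3 -i3-> g4
chain_map <- function() {
  symbol_map("C", list(list(src = "g1", tgt = "g2"),
                       list(src = "g2", tgt = "g3"),
                       list(src = "g3", tgt = "g4")))
}

cycle_map <- function(id = "Y") {
  symbol_map(id, list(list(src = "c1", tgt = "c2"),
                      list(src = "c2", tgt = "c3"),
                      list(src = "c3", tgt = "c1")))
}

test_that("reaction graph edge rule: target feeds source/modifier, canonical identity", {
  m <- chain_map()
  g <- build_reaction_graph(m)
  expect_setequal(paste(g$edges$from, g$edges$to),
                  c("C_i01 C_i02", "C_i02 C_i03"))
  sccs <- strongly_connected_components(g)
  expect_length(sccs, 3)   # acyclic chain: three singletons
  expect_true(all(vapply(sccs, function(s) length(s$members), 0L) == 1))
  # feedback cycle collapses into one 3-member SCC
  gc <- build_reaction_graph(cycle_map())
  sc <- strongly_connected_components(gc)
  expect_length(sc, 1)
  expect_length(sc[[1]]$members, 3)
  # modifiers receive edges too
  mm <- symbol_map("M", list(list(src = "a", tgt = "b"),
                             list(src = "x", tgt = "y", mod = "b")))
  gm <- build_reaction_graph(mm)
  expect_equal(paste(gm$edges$from, gm$edges$to), "M_i01 M_i02")
  # identity is canonical id: same symbol in different diagrams connects
  md <- mk_map("D", list(el("e1", "s1", dia = "d1"), el("e2", "s2", dia = "d1"),
                         el("e3", "s2", dia = "d2"), el("e4", "s3", dia = "d2")),
               list(ix("i1", "e1", "e2", dia = "d1"),
                    ix("i2", "e3", "e4", dia = "d2")))
  gd <- build_reaction_graph(md)
  expect_equal(paste(gd$edges$from, gd$edges$to), "i1 i2")
  # self-loop only when an interaction's target feeds its own sources
  ms <- symbol_map("S", list(list(src = "u", tgt = "u")))
  gs <- build_reaction_graph(ms)
  expect_equal(nrow(gs$edges), 1)
  expect_equal(gs$edges$from, gs$edges$to)
  expect_error(build_reaction_graph(m, "ghost"), "unknown")
})

test_that("SCCs: empty graph, complete digraph, restriction", {
  empty <- mk_map("E", list(el("e1", "x")), list())
  expect_length(strongly_connected_components(build_reaction_graph(empty)), 0)
  # complete digraph on 4 nodes via a common hub symbol set
  edges <- lapply(1:4, function(k) list(src = "h", tgt = "h"))
  m4 <- symbol_map("K", edges)
  g4 <- build_reaction_graph(m4)
  s4 <- strongly_connected_components(g4)
  expect_length(s4, 1)
  expect_length(s4[[1]]$members, 4)
  # restrict_to drops nodes (and their edges)
  g2 <- build_reaction_graph(m4, c("K_i01", "K_i02"))
  expect_length(g2$nodes, 2)
})

test_that("SCC partition equals the transitive-closure oracle on random digraphs", {
  set.seed(2024)
  for (rep in 1:60) {
    n <- sample(2:12, 1)
    rg <- random_digraph(n, p = stats::runif(1, 0.05, 0.4))
    g <- structure(list(map_id = "R", nodes = rg$nodes,
                        edges = rg$edges), class = "reaction_graph")
    got <- lapply(strongly_connected_components(g), `[[`, "members")
    want <- scc_oracle(rg$nodes, rg$edges)
    expect_identical(partition_key(got), partition_key(want))
    # partition property: disjoint and covering
    all_members <- unlist(got)
    expect_identical(sort(all_members, method = "radix"),
                     sort(rg$nodes, method = "radix"))
  }
})

test_that("weak mode unites cascades that strict SCCs keep apart", {
  g <- build_reaction_graph(chain_map())
  expect_length(strongly_connected_components(g, "strong"), 3)
  weak <- strongly_connected_components(g, "weak")
  expect_length(weak, 1)
  expect_length(weak[[1]]$members, 3)
})

test_that("SCC pairs need min_similar_reactions matched pairs to group", {
  mk_cycle_pair <- function(k) {
    syms <- sprintf("q%02d", seq_len(k))
    edges <- lapply(seq_len(k), function(j) {
      list(src = syms[j], tgt = syms[if (j == k) 1 else j + 1])
    })
    list(a = symbol_map("A", edges), b = symbol_map("B", edges))
  }
  # 4 matched reactions in one SCC pair: no group at the default of 5
  p4 <- mk_cycle_pair(4)
  r4 <- similarity_groups(p4$a, p4$b)
  expect_equal(nrow(r4$matches), 4)
  expect_length(r4$groups, 0)
  # 5 matched reactions: exactly one group
  p5 <- mk_cycle_pair(5)
  r5 <- similarity_groups(p5$a, p5$b)
  expect_length(r5$groups, 1)
  expect_equal(r5$groups[[1]]$n_similar, 5)
  # no matches at all -> empty group list
  da <- symbol_map("A", list(list(src = "only_a1", tgt = "only_a2")))
  db <- symbol_map("B", list(list(src = "only_b1", tgt = "only_b2")))
  r0 <- similarity_groups(da, db)
  expect_length(r0$groups, 0)
})

test_that("one planted 6-cycle yields exactly one group with all 6 matches", {
  pair <- generate_map_pair(sim_config(seed = 13, n_planted_modules = 1,
                                       module_size = 6))
  res <- similarity_groups(pair$map_a, pair$map_b)
  expect_length(res$groups, 1)
  g <- res$groups[[1]]
  expect_equal(g$n_similar, 6)
  mod <- pair$truth$planted_module_pairs[[1]]
  expect_setequal(g$scc_a$members, mod$interactions_a)
  expect_setequal(g$scc_b$members, mod$interactions_b)
  # group matches are a subset of the global match list
  glob <- paste(res$matches$interaction_a, res$matches$interaction_b)
  expect_true(all(paste(g$matches$interaction_a, g$matches$interaction_b)
                  %in% glob))
  cov <- group_coverage(res$groups, pair$map_a, pair$map_b)
  expect_equal(cov$n_covered_a, 6)
  expect_equal(cov$n_covered_b, 6)
  expect_equal(cov$total_a, nrow(pair$map_a$interactions))
})

test_that("coverage is monotone as thresholds relax", {
  pair <- generate_map_pair(sim_config(seed = 17, corruption_rate = 0.15))
  cov_n <- function(min_sim, min_reac) {
    cfg <- comparison_config(min_similarity = min_sim,
                             min_similar_reactions = min_reac)
    res <- similarity_groups(pair$map_a, pair$map_b, cfg)
    group_coverage(res$groups, pair$map_a, pair$map_b)$n_covered_a
  }
  expect_lte(cov_n(0.9, 5), cov_n(0.7, 5))
  expect_lte(cov_n(0.7, 5), cov_n(0.5, 5))
  expect_lte(cov_n(0.7, 6), cov_n(0.7, 5))
  expect_lte(cov_n(0.7, 5), cov_n(0.7, 3))
})

test_that("element frequency counts one hit per group", {
  pair <- generate_map_pair(sim_config(seed = 19, n_planted_modules = 4,
                                       module_size = 5))
  res <- similarity_groups(pair$map_a, pair$map_b)
  expect_length(res$groups, 4)
  freq <- element_group_frequency(res$groups, pair$map_a, pair$map_b)
  # module symbols are module-private: every key occurs in exactly 1 group
  expect_true(all(freq$n_groups == 1))
  mod_keys <- unlist(lapply(pair$truth$planted_module_pairs, `[[`, "symbols"))
  expect_setequal(freq$key, mod_keys)
  # a symbol present in several groups counts once per group: share one
  # symbol across two hand-built grouped cycles
  edges1 <- lapply(1:5, function(j) list(src = sprintf("m%d", j),
                                         tgt = sprintf("m%d", j %% 5 + 1)))
  edges2 <- lapply(1:5, function(j) list(src = sprintf("n%d", j),
                                         tgt = sprintf("n%d", j %% 5 + 1)))
  edges2[[1]]$mod <- "m1"   # m1 also appears in cycle 2
  a <- symbol_map("A", c(edges1, edges2))
  b <- symbol_map("B", c(edges1, edges2))
  res2 <- similarity_groups(a, b)
  freq2 <- element_group_frequency(res2$groups, a, b)
  expect_equal(freq2$n_groups[freq2$key == "HGNC:M1"], 2)
  expect_equal(freq2$key[1], "HGNC:M1")  # ranked first
})

test_that("disease-specific clusters are the unmatched complement", {
  pair <- generate_map_pair(sim_config(seed = 23, n_background_interactions = 10))
  matches <- match_interactions(pair$map_a, pair$map_b)
  cl <- disease_specific_clusters(pair$map_a, matches, side = "a")
  members <- unlist(lapply(cl, `[[`, "members"))
  planted_a <- unlist(lapply(pair$truth$planted_module_pairs,
                             `[[`, "interactions_a"))
  expect_length(intersect(members, planted_a), 0)
  expect_setequal(members,
                  setdiff(pair$map_a$interactions$interaction_id, planted_a))
  # fully matched map: empty cluster list
  a <- cycle_map("A"); b <- cycle_map("B")
  m_all <- match_interactions(a, b)
  expect_length(disease_specific_clusters(a, m_all, side = "a"), 0)
  # a specific background cycle comes back as one cluster
  edges <- lapply(1:4, function(j) list(src = sprintf("w%d", j),
                                        tgt = sprintf("w%d", j %% 4 + 1)))
  lone <- symbol_map("L", edges)
  cl2 <- disease_specific_clusters(lone, match_interactions(lone, b), "a")
  expect_length(cl2, 1)
  expect_length(cl2[[1]]$members, 4)
})

test_that("group outputs serialize to TSV and JSON", {
  pair <- generate_map_pair(sim_config(seed = 29, n_planted_modules = 2))
  res <- similarity_groups(pair$map_a, pair$map_b)
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  write_groups(res, pair$map_a, pair$map_b, tsv, js)
  tab <- utils::read.delim(tsv, stringsAsFactors = FALSE)
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$n_similar >= 5))
  doc <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_equal(doc$component_mode, "strong")
  expect_equal(doc$n_groups, 2)
  expect_length(doc$groups, 2)
})
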