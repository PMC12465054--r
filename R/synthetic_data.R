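# Seeded generator for pairs of disease maps with known ground truth:
# cell-type compartments with controlled identifier overlap, planted
# shared cyclic interaction modules, map-specific background interactions,
# optional corruption of planted interactions, and a truth manifest.

#' Simulation configuration for a synthetic map pair
#'
#' The stated world the generator emulates: two multi-diagram maps with
#' cell-type compartments holding HGNC-annotated proteins, a controllable
#' fraction of identifiers shared between maps, and planted shared
#' interaction modules arranged as directed cycles (so they form strongly
#' connected components of configurable size).
#'
#' @param seed Integer seed; all randomness flows from it.
#' @param n_cell_types_per_map Cell types (pathway diagrams) per map.
#' @param n_shared_cell_types How many cell types occur in both maps.
#' @param proteins_per_cell_type Profile size per cell type.
#' @param identifier_overlap_fraction Fraction of each shared cell type's
#'   profile drawn from the shared vocabulary.
#' @param n_planted_modules Number of planted shared modules.
#' @param module_size Interactions per planted module (cyclic).
#' @param n_background_interactions Map-specific background interactions
#'   per map, over a vocabulary disjoint between the maps.
#' @param corruption_rate Fraction of map B's planted interactions whose
#'   participants are replaced with map-specific noise identifiers.
#' @param acyclic_modules If `TRUE`, planted modules are open cascades
#'   (chains) instead of cycles — exercises the weak-component fallback.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_cell_types_per_map = 5,
                       n_shared_cell_types = 3, proteins_per_cell_type = 12,
                       identifier_overlap_fraction = 0.5,
                       n_planted_modules = 3, module_size = 6,
                       n_background_interactions = 30, corruption_rate = 0,
                       acyclic_modules = FALSE) {
  cfg <- list(seed = as.integer(seed),
              n_cell_types_per_map = as.integer(n_cell_types_per_map),
              n_shared_cell_types = as.integer(n_shared_cell_types),
              proteins_per_cell_type = as.integer(proteins_per_cell_type),
              identifier_overlap_fraction = identifier_overlap_fraction,
              n_planted_modules = as.integer(n_planted_modules),
              module_size = as.integer(module_size),
              n_background_interactions = as.integer(n_background_interactions),
              corruption_rate = corruption_rate,
              acyclic_modules = isTRUE(acyclic_modules))
  with(cfg, {
    stopifnot(n_cell_types_per_map >= 0, proteins_per_cell_type >= 0,
              n_planted_modules >= 0, n_background_interactions >= 0,
              identifier_overlap_fraction >= 0, identifier_overlap_fraction <= 1,
              corruption_rate >= 0, corruption_rate <= 1)
    if (n_shared_cell_types > n_cell_types_per_map) {
      stop("infeasible config: n_shared_cell_types (", n_shared_cell_types,
           ") exceeds n_cell_types_per_map (", n_cell_types_per_map, ")")
    }
    if (n_planted_modules > 0 && module_size < 1) {
      stop("infeasible config: planted modules need module_size >= 1")
    }
  })
  structure(cfg, class = "sim_config")
}

# run expr with a private RNG stream seeded from `seed`
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic disease-map pair with ground truth
#'
#' Builds two maps under `cfg` (see [sim_config()]):
#' \itemize{
#'   \item Each map has one intercellular (main) diagram plus one pathway
#'     diagram per cell type; profile proteins sit in their cell type's
#'     compartment.
#'   \item Shared cell types draw `round(f * P)` of their `P` profile
#'     symbols from a common vocabulary, the rest map-specific, so the
#'     expected cross-map profile Jaccard is `s / (2P - s)` exactly.
#'   \item Planted modules are directed interaction cycles duplicated in
#'     both maps with identical participant identifiers, placed on the
#'     main diagrams; they are the ground-truth similarity groups.
#'   \item Background interactions connect map-specific vocabularies
#'     (disjoint between maps) and can never match across maps.
#'   \item Corruption replaces the participants of a deterministic count
#'     (`round(rate * n_planted)`) of map B's planted interactions with
#'     fresh noise identifiers, breaking those matches.
#' }
#' Identical configurations (including the seed) yield byte-identical
#' maps and manifest.
#'
#' @param cfg A [sim_config()].
#' @return A list with `map_a`, `map_b` (validated `disease_map`s) and
#'   `truth`, the manifest: `planted_module_pairs` (per module: the
#'   interaction ids in each map and the corrupted ids), the exact
#'   `shared_identifier_set`, `shared_cell_types` with their expected
#'   Jaccard values, `druggable_shared_targets` and a matching
#'   `drug_targets` record table.
#' @export
generate_map_pair <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_local_seed(cfg$seed, generate_map_pair_impl(cfg))
}

generate_map_pair_impl <- function(cfg) {
  shared_ctr <- 0L
  next_shared <- function(n) {
    v <- sprintf("GENE%04d", shared_ctr + seq_len(n))
    shared_ctr <<- shared_ctr + n
    v
  }
  side_ctr <- c(A = 0L, B = 0L)
  next_side <- function(side, n, prefix = "GENE") {
    v <- sprintf("%s%s%04d", side, prefix, side_ctr[[side]] + seq_len(n))
    side_ctr[[side]] <<- side_ctr[[side]] + n
    v
  }

  S <- cfg$n_shared_cell_types
  C <- cfg$n_cell_types_per_map
  P <- cfg$proteins_per_cell_type
  s_shared <- round(cfg$identifier_overlap_fraction * P)

  shared_cts <- sprintf("CellTypeS%02d", seq_len(S))
  spec_a <- sprintf("CellTypeA%02d", seq_len(C - S))
  spec_b <- sprintf("CellTypeB%02d", seq_len(C - S))

  # profiles: cell type -> symbol vector, per map
  prof_a <- list(); prof_b <- list()
  for (ct in shared_cts) {
    com <- next_shared(s_shared)
    prof_a[[ct]] <- c(com, next_side("A", P - s_shared))
    prof_b[[ct]] <- c(com, next_side("B", P - s_shared))
  }
  for (ct in spec_a) prof_a[[ct]] <- next_side("A", P)
  for (ct in spec_b) prof_b[[ct]] <- next_side("B", P)

  # planted modules: shared symbol cycles (chains when acyclic)
  k <- cfg$module_size
  n_sym <- if (cfg$acyclic_modules) k + 1L else k
  modules <- lapply(seq_len(cfg$n_planted_modules), function(m) {
    syms <- next_shared(n_sym)
    steps <- lapply(seq_len(k), function(j) {
      c(syms[j], syms[if (j == k && !cfg$acyclic_modules) 1L else j + 1L])
    })
    list(module_id = sprintf("M%02d", m), symbols = syms, steps = steps)
  })

  # interaction participant plans per map: list of (id, diagram, src_sym, tgt_sym)
  plan_side <- function(side, profs, cts_spec) {
    rows <- list()
    for (m in modules) {
      for (j in seq_along(m$steps)) {
        rows[[length(rows) + 1L]] <- list(
          id = sprintf("%s_i_%s_%02d", side, m$module_id, j),
          diagram = "main", src = m$steps[[j]][1], tgt = m$steps[[j]][2],
          planted = m$module_id)
      }
    }
    rows
  }
  plan_a <- plan_side("A", prof_a, spec_a)
  plan_b <- plan_side("B", prof_b, spec_b)

  # corruption: deterministic count of B's planted interactions perturbed
  n_planted_b <- length(plan_b)
  n_corrupt <- round(cfg$corruption_rate * n_planted_b)
  corrupted_ids <- character()
  if (n_corrupt > 0) {
    pick <- sort(sample.int(n_planted_b, n_corrupt))
    noise <- next_side("B", 2L * n_corrupt, prefix = "NOISE")
    for (h in seq_along(pick)) {
      j <- pick[h]
      plan_b[[j]]$src <- noise[2L * h - 1L]
      plan_b[[j]]$tgt <- noise[2L * h]
      corrupted_ids <- c(corrupted_ids, plan_b[[j]]$id)
    }
  }

  # background interactions over map-specific background vocabularies
  add_background <- function(side, plan) {
    nb <- cfg$n_background_interactions
    if (nb == 0) return(list(plan = plan, syms = character()))
    syms <- next_side(side, nb + 1L, prefix = "BKG")
    for (j in seq_len(nb)) {
      pick <- sample.int(length(syms), 2L)
      plan[[length(plan) + 1L]] <- list(
        id = sprintf("%s_i_bkg_%03d", side, j), diagram = "main",
        src = syms[pick[1]], tgt = syms[pick[2]], planted = NA_character_)
    }
    list(plan = plan, syms = syms)
  }
  bg_a <- add_background("A", plan_a); plan_a <- bg_a$plan
  bg_b <- add_background("B", plan_b); plan_b <- bg_b$plan

  build_map <- function(side, label, cts, profs, plan) {
    diagrams <- rbind(
      data.frame(diagram_id = "main", name = "Intercellular layer",
                 kind = "INTERCELLULAR", cell_type = "",
                 stringsAsFactors = FALSE),
      if (length(cts)) data.frame(diagram_id = paste0("d_", cts), name = cts,
                                  kind = "PATHWAY", cell_type = cts,
                                  stringsAsFactors = FALSE))
    # elements: profile proteins in their compartments + symbols used on main
    el <- list()
    eid <- 0L
    el_of_main <- new.env(parent = emptyenv())
    add_el <- function(sym, diagram, compartment) {
      eid <<- eid + 1L
      id <- sprintf("%s_e%04d", side, eid)
      el[[length(el) + 1L]] <<- list(element_id = id, display_name = sym,
                                     entity_class = "PROTEIN",
                                     diagram_id = diagram,
                                     compartment = compartment,
                                     annotations = data.frame(
                                       namespace = "HGNC", value = sym,
                                       stringsAsFactors = FALSE))
      id
    }
    for (ct in cts) for (sym in profs[[ct]]) add_el(sym, paste0("d_", ct), ct)
    main_el <- function(sym) {
      if (!exists(sym, envir = el_of_main, inherits = FALSE)) {
        assign(sym, add_el(sym, "main", ""), envir = el_of_main)
      }
      get(sym, envir = el_of_main, inherits = FALSE)
    }
    ints <- lapply(plan, function(p) {
      list(interaction_id = p$id, diagram_id = p$diagram, sign = "POSITIVE",
           sources = main_el(p$src), targets = main_el(p$tgt),
           modifiers = character(), references = character())
    })
    elements <- data.frame(
      element_id = vapply(el, `[[`, "", "element_id"),
      display_name = vapply(el, `[[`, "", "display_name"),
      entity_class = vapply(el, `[[`, "", "entity_class"),
      diagram_id = vapply(el, `[[`, "", "diagram_id"),
      compartment = vapply(el, `[[`, "", "compartment"),
      stringsAsFactors = FALSE)
    elements$annotations <- I(lapply(el, `[[`, "annotations"))
    interactions <- data.frame(
      interaction_id = vapply(ints, `[[`, "", "interaction_id"),
      diagram_id = vapply(ints, `[[`, "", "diagram_id"),
      sign = vapply(ints, `[[`, "", "sign"), stringsAsFactors = FALSE)
    interactions$sources <- I(lapply(ints, `[[`, "sources"))
    interactions$targets <- I(lapply(ints, `[[`, "targets"))
    interactions$modifiers <- I(lapply(ints, `[[`, "modifiers"))
    interactions$references <- I(lapply(ints, `[[`, "references"))
    disease_map(paste0("SYN_", side), label, diagrams, elements, interactions)
  }

  map_a <- build_map("A", "synthetic disease A", c(shared_cts, spec_a),
                     prof_a, plan_a)
  map_b <- build_map("B", "synthetic disease B", c(shared_cts, spec_b),
                     prof_b, plan_b)

  # shared identifiers, constructively: shared profile symbols plus module
  # symbols still used by at least one uncorrupted interaction of B
  used_b <- unique(unlist(lapply(plan_b, function(p) c(p$src, p$tgt))))
  shared_profile <- unlist(lapply(shared_cts,
                                  function(ct) intersect(prof_a[[ct]], prof_b[[ct]])))
  module_syms <- unique(unlist(lapply(modules, `[[`, "symbols")))
  shared_syms <- unique(c(shared_profile, intersect(module_syms, used_b)))
  shared_keys <- if (length(shared_syms)) {
    sort_c(paste0("HGNC:", shared_syms))
  } else {
    character()
  }

  exp_jac <- if (P == 0) 0 else s_shared / (2 * P - s_shared)
  planted_pairs <- lapply(modules, function(m) {
    ia <- sprintf("A_i_%s_%02d", m$module_id, seq_len(k))
    ib <- sprintf("B_i_%s_%02d", m$module_id, seq_len(k))
    list(module_id = m$module_id, interactions_a = ia, interactions_b = ib,
         corrupted_b = intersect(ib, corrupted_ids),
         symbols = paste0("HGNC:", m$symbols))
  })

  druggable <- sort_c(unique(unlist(lapply(modules, function(m) {
    intersect(paste0("HGNC:", m$symbols[seq_len(min(2L, length(m$symbols)))]),
              shared_keys)
  }))))
  drug_targets <- synthetic_drug_table(modules)

  truth <- list(planted_module_pairs = planted_pairs,
                shared_identifier_set = shared_keys,
                shared_cell_types = data.frame(
                  cell_type = shared_cts,
                  expected_jaccard = rep(exp_jac, length(shared_cts)),
                  stringsAsFactors = FALSE),
                druggable_shared_targets = druggable,
                drug_targets = drug_targets)
  list(map_a = map_a, map_b = map_b, truth = truth)
}

# one two-target drug per module, one single-target decoy, one off-map decoy
synthetic_drug_table <- function(modules) {
  rows <- list()
  for (m in modules) {
    syms <- m$symbols[seq_len(min(2L, length(m$symbols)))]
    for (sym in syms) {
      rows[[length(rows) + 1L]] <- data.frame(
        drug_id = paste0("DB_", m$module_id), drug_name = paste0("drug_", m$module_id),
        source_db = "DRUGBANK", target_symbol = sym, evidence = "synthetic",
        stringsAsFactors = FALSE)
    }
  }
  if (length(modules)) {
    rows[[length(rows) + 1L]] <- data.frame(
      drug_id = "DB_SINGLE", drug_name = "single_target_decoy",
      source_db = "CHEMBL", target_symbol = modules[[1]]$symbols[1],
      evidence = "synthetic", stringsAsFactors = FALSE)
  }
  rows[[length(rows) + 1L]] <- data.frame(
    drug_id = "DB_OFFMAP", drug_name = "off_map_decoy", source_db = "CHEMBL",
    target_symbol = "NOTINANYMAP1", evidence = "synthetic",
    stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

#' Write the synthetic drug-target fixture table
#'
#' Emits `truth$drug_targets` in the TSV dialect read by
#' [load_drug_targets()].
#'
#' @param truth Truth manifest from [generate_map_pair()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_drug_fixture <- function(truth, path) {
  utils::write.table(truth$drug_targets, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Module-level recovery of planted ground truth
#'
#' A planted module counts as recovered when some similarity group
#' contains at least half of its planted interaction pairs. Precision is
#' the fraction of groups supported by a recovered module; recall the
#' fraction of planted modules recovered. With zero groups and zero
#' planted modules both are 1 by convention (nothing was missed and
#' nothing spurious was reported); zero groups alone gives precision 1.
#'
#' @param groups Group list from [pair_components()] computed on a
#'   generated pair.
#' @param truth The pair's truth manifest.
#' @return A list with `precision` and `recall`.
#' @export
evaluate_recovery <- function(groups, truth) {
  mods <- truth$planted_module_pairs
  if (length(groups) == 0) {
    return(list(precision = 1, recall = if (length(mods) == 0) 1 else 0))
  }
  group_pairs <- lapply(groups, function(g) {
    paste(g$matches$interaction_a, g$matches$interaction_b, sep = "\r")
  })
  module_hit <- logical(length(mods))
  group_supported <- logical(length(groups))
  for (mi in seq_along(mods)) {
    m <- mods[[mi]]
    planted <- paste(m$interactions_a, m$interactions_b, sep = "\r")
    need <- length(planted) / 2
    for (gi in seq_along(groups)) {
      if (sum(planted %in% group_pairs[[gi]]) >= need) {
        module_hit[mi] <- TRUE
        group_supported[gi] <- TRUE
      }
    }
  }
  list(precision = mean(group_supported),
       recall = if (length(mods) == 0) 1 else mean(module_hit))
}
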