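---
title: "Comparing annotated disease maps with dmcompare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing annotated disease maps with dmcompare}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmcompare)
```

## The problem

Curated disease maps encode the molecular mechanisms of a disease as
multi-diagram activity-flow networks: an intercellular layer of cell
types exchanging cytokines and other mediators, plus cell type-specific
pathway diagrams. Two maps built independently for two immune-mediated
diseases (say, an inflammatory bowel disease and an inflammatory skin
disease) will share machinery — T-helper cytokine programs, NF-κB and
JAK-STAT signalling — alongside disease-specific biology. `dmcompare`
quantifies that overlap at three resolutions:

1. **Identifiers** — which gene products, metabolites and phenotypes
   occur in both maps, per map and per diagram;
2. **Cell types** — Jaccard similarity of per-compartment protein
   profiles;
3. **Mechanisms** — groups of interactions that are similar between the
   maps and topologically cohesive within each map, found by matching
   interactions across maps and intersecting the result with strongly
   connected components (SCCs) of each map's reaction-adjacency graph.

A drug-target projection then asks which shared mechanisms are already
druggable, and an overlay builder renders external evidence (variant
lists, differential expression) on the maps in the MINERVA data-overlay
dialect.

## The comparison key: canonical identifiers

Elements drawn in different diagrams are the same biological entity when
their stable identifiers agree. The canonical identifier of an element is

* its uppercased **HGNC symbol** for PROTEIN / GENE / RNA elements,
* its **ChEBI id** for simple molecules,
* its lowercased, whitespace-collapsed display name for **phenotypes**.

Complexes carry no canonical identifier of their own (their subunits do,
when drawn separately); unannotated gene products are excluded from all
identifier analyses. When an element carries several annotations in one
namespace, the first wins and a warning is raised. All identifier-level
statistics (`unique_identifiers()`, `shared_identifiers()`,
`diagram_overlap_matrix()`, `symbol_incidence()`) default to HGNC
symbols only — the stable, curated namespace — and can be widened to
ChEBI/name via the `namespaces` argument.

## Interaction matching

Each interaction is reduced to its **participant set**: the canonical
identifiers of its sources, targets and modifiers, deduplicated.
Modifiers are included by default because a kinase regulating a reaction
is part of the mechanism; `comparison_config(include_modifiers = FALSE)`
excludes them. Similarity between a cross-map interaction pair is the
Jaccard index of the two participant sets. The upstream workflow this
package re-implements does not print its exact formula, so role-agnostic
Jaccard was chosen as the simplest metric consistent with the two
published filter semantics, which are reproduced exactly:

* similarity **≥ 0.7**, and
* **at least two** matching elements — a pair sharing a single element is
  rejected even at similarity 1.0.

Both thresholds are inclusive; a similarity that *is* the threshold
(e.g. 7 shared of 10) is accepted, guarded against floating-point
representation by a 1e-9 slack. A `role_strict` variant counts only
identifiers occupying the same role on both sides, and `require_sign`
demands sign agreement; both are off by default since the published
filters mention neither. Candidate pairs are enumerated through an
inverted index on canonical identifiers, so only pairs sharing at least
one identifier are scored; since every retained match shares at least
`min_shared_elements ≥ 1` identifiers, no retained match can be lost.

## Similarity groups

Within each map a **reaction graph** is built on the matched
interactions: edge A→B whenever a canonical identifier among A's targets
occurs among B's sources or modifiers. Identity is canonical, not
element-level, so cascades spanning diagrams (a cytokine produced in one
cell type acting in another) connect. SCCs of this graph delimit
feedback-closed modules; an SCC pair (one per map) linked by **five or
more** distinct matched interaction pairs is a similarity group. One SCC
may pair with several opposite SCCs; within a map SCCs are disjoint.

Two counting conventions were genuinely open:

* *"five or more similar reactions"* is counted as distinct matched
  **pairs** (the alternative — distinct reactions on one side — is
  equivalent when matches are one-to-one, as they are for the planted
  modules of the generator);
* group **coverage** counts the distinct interactions in the union of
  each group's SCC members (the group's visible map area), not only
  matched endpoints.

Signalling cascades without feedback produce singleton SCCs and can
never reach five similar reactions. For such maps
`comparison_config(component_mode = "weak")` switches to weakly
connected components; the mode used is always recorded in the group
JSON and run report. Strict SCC remains the default, matching the
published wording. Interactions with *no* cross-map match are clustered
the same way by `disease_specific_clusters()` — the mechanisms unique to
one disease.

## Data overlays

Variant overlays are qualitative: one entry per gene affected by at
least one disease-associated variant, value 1, fixed colour (the
numeric encoding is this package's convention; the source analysis does
not state one). Expression overlays scale log fold changes by
**max-absolute scaling** — `x / max(|x|)` per dataset — because unlike
min-max scaling it preserves sign, zero and magnitude order, which a
diverging colour scale requires. Scaling is idempotent and invariant
under positive rescaling; an all-zero vector stays zero. `write_overlay()`
refuses values outside [-1, 1], catching unscaled input at the boundary.

## Drug-target projection

Drug-target tables are consumed from TSV files only (DrugBank licensing
forbids redistribution; live queries are out of scope), with targets
normalized to HGNC keys. A target is "in" a group when it participates
in any interaction of either SCC of the group. `shared_drug_targets()`
reports targets present on *both* maps' sides of at least one group;
`group_drug_reports()` keeps, per group, the drugs hitting at least two
distinct targets inside that group. Absolute target/drug counts from
the source analysis are snapshot-dependent (database versions are not
recorded there) and are deliberately not reproduced.

## The synthetic world

`generate_map_pair()` emits a pair of maps whose ground truth is known
exactly, so every stage is testable offline:

* `n_cell_types_per_map = 5` cell types per map, `n_shared_cell_types = 3`
  present in both; each holds `proteins_per_cell_type = 12` proteins in
  its pathway diagram's compartment.
* For a shared cell type, `round(f · P)` of its `P` profile symbols come
  from a common vocabulary (`identifier_overlap_fraction f = 0.5` by
  default), giving expected cross-map profile Jaccard `s / (2P − s)`
  with **no sampling noise** — the manifest states the realized truth.
* `n_planted_modules = 3` modules of `module_size = 6` interactions are
  duplicated across maps with identical participant identifiers and
  wired as directed cycles, so each forms an SCC and a recoverable
  group; `acyclic_modules = TRUE` plants open cascades instead, to
  exercise the weak-component mode.
* `n_background_interactions = 30` per map connect map-specific
  vocabularies, disjoint between maps — they can never match and become
  disease-specific clusters.
* `corruption_rate` replaces the participants of `round(rate · n)` of
  map B's planted interactions with fresh noise identifiers, breaking
  those matches (and, for cycles, the SCC), so recall degrades with the
  rate.

The defaults are a scaled-down analogue of the real maps (19 cell types,
800–1250 interactions, roughly half of the gene-level identifier union
shared): small enough for sub-second generation, large enough that every
threshold in the pipeline is exercised away from degenerate edges. What
the generator does **not** emulate: literature references, layout,
multi-role participants, complexes/metabolites (all planted elements are
HGNC proteins), and hub promiscuity — real maps share identifiers across
*unrelated* interactions, so a green planted-module test establishes
correct mechanics and thresholds, not performance on adversarial
topology. All randomness flows from the single `seed` through one
private RNG stream (the caller's RNG state is untouched), and identical
configurations yield byte-identical files.

Module recovery is scored by `evaluate_recovery()`: a module is
recovered when some group contains at least half of its planted
interaction pairs; precision is the fraction of groups supported by a
recovered module, recall the fraction of modules recovered; with zero
groups and zero planted modules both are 1 by convention.

## Numerical and formatting choices

* All ranked outputs break ties lexicographically (C-collation radix
  sort, locale-independent) after the primary key, so every table and
  file is byte-stable across runs and platforms.
* `J(∅, ∅) = 0`, not `NaN`: an empty compartment should not report
  self-similarity. The Jaccard omission threshold is inclusive
  (`value ≤ 0.05` is omitted), and omitted cells keep their numeric
  value alongside the flag.
* The native map format is versioned JSON mirroring the in-memory model;
  records serialize in canonical id order. CellDesigner SBML parsing is
  out of scope — the deposited maps are accessed via MINERVA project
  exports, for which `read_minerva_export()` documents a field-by-field
  mapping and drops unparseable records into a load report rather than
  failing wholesale (dangling participant references, by contrast, are
  fatal).
* The run report (`run_compare()`) omits timestamps so identical inputs
  give byte-identical reports; input provenance is carried by MD5
  checksums instead.

## A worked run

```{r example}
pair <- generate_map_pair(sim_config(seed = 1))
length(shared_identifiers(pair$map_a, pair$map_b))
res <- similarity_groups(pair$map_a, pair$map_b)
length(res$groups)
evaluate_recovery(res$groups, pair$truth)
```

## Known limitations

* Identifier comparison trusts curation: no synonym resolution or
  remapping via external HGNC services.
* The similarity metric is a design choice standing in for an unprinted
  upstream formula; role- or class-weighted variants would change group
  composition at the margins (the filter semantics would not).
* Interaction-level SCCs are one of two plausible graph levels (the
  other being element-level); the interaction level is implemented
  because groups are defined over reactions.
* Drug analysis reports structure (which groups are druggable, by what),
  not database-version-dependent totals.
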