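Package: dmcompare
Title: Cross-Disease Comparison of Annotated Molecular Disease Maps
Version: 0.1.0
Authors@R: person("Map", "Comparison Team", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the systematic comparison of two curated molecular
    disease maps (multi-diagram, SBGN Activity Flow style networks with
    HGNC/ChEBI-annotated elements and signed directed interactions).
    Computes shared and disease-specific identifier sets, per-diagram
    overlap matrices, cell-type protein profiles with Jaccard similarity,
    cross-map interaction matches filtered by participant-set similarity,
    strongly-connected-component similarity groups, drug-target projections
    onto those groups, and MINERVA-dialect data overlays from variant lists
    and differential-expression tables. Includes a seeded synthetic
    map-pair generator with a ground-truth manifest so every pipeline stage
    is testable without network access.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    igraph,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
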