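Package: histonet
Title: Multi-Evidence Protein Interactome Construction Around Histones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds protein-, domain-, and residue-level interaction
    networks around a focal protein family (human histones as the shipped
    exemplar) from three evidence sources: structural complexes in
    PDBx/mmCIF format (5 Angstrom heavy-atom interface extraction with
    SIFTS-style residue mapping), cross-linking mass spectrometry records,
    and binary high-throughput protein-protein interactions. Core networks
    can be expanded into global interactomes by one layer of
    partner-of-partner interactions and merged across evidence sources
    with accession-level deduplication. Networks are exported in open
    graph formats (GraphML, SIF, JSON graph, edge tables) loadable by
    Cytoscape. A deterministic fixture generator produces synthetic
    structures and evidence tables with independently computed expected
    outputs, so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
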