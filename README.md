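# histonet

Construction of protein-, domain-, and residue-level interaction
networks around a focal protein family — human histones in the shipped
configuration — from three complementary evidence sources:

* **structural**: PDBx/mmCIF biological assemblies, from which binding
  interfaces are extracted as residues with at least one heavy atom
  within 5 Å of a partner chain's heavy atoms (inclusive, double
  precision), then mapped to UniProt coordinates through a SIFTS-style
  residue mapping table;
* **cross-linking MS**: inter-protein lysine–lysine cross-link records,
  giving both protein-level interactions and residue-level interface
  positions;
* **binary high-throughput PPIs**: APID-style interaction tables
  filtered to direct physical ("binary") detection methods such as
  yeast two-hybrid.

Each source yields a *core* network of histone × non-histone edges with
full evidence provenance per edge. Core networks can be expanded by one
layer of partner-of-partner interactions (*global* interactomes),
collapsed from proteins to conserved-domain families, and merged across
sources with accession-level node deduplication. Networks are exported
as GraphML, JSON graph (both lossless round-trip formats), SIF and edge
tables — all loadable by Cytoscape.

Who this is for: chromatin and structural-bioinformatics groups who want
a reproducible, offline, tested pipeline for building and combining
focal-protein interactomes from locally supplied structure files and
evidence tables.

## The core operation

For a histone chain H and partner chain P, the interface is

    I(H, P) = { (i, j) : min over heavy atoms a∈H_i, b∈P_j of d(a, b) ≤ 5.0 Å }

computed over all residue pairs (i, j), with hydrogens and deuteriums
excluded, alternate locations resolved to the highest-occupancy
conformer, and the biological assembly expanded from its symmetry
operators. The protein-level edge (H, P) accumulates one structural
evidence item per contributing structure; the residue-level network
keeps each interface residue pair as an `accession:position` node pair.
Every builder obeys the same interaction definition — exactly one
endpoint is a catalog histone — and every output passes
`validate_network()`.

## Worked example

The package ships a deterministic fixture generator, so the whole
pipeline runs without any downloads:

```r
library(histonet)

fx <- generate_fixture_suite(seed = 1, profile = "minimal", dir = "fx")
catalog <- read_histone_catalog(fx$files$catalog)
chains  <- parse_structure_cif(fx$files$cif)

report <- apply_curation_filters(list(FX01 = chains), catalog)
report
#> <curation_report> 1 structures: 1 retained, 0 excluded

nets <- build_structural_networks(
  list(FX01 = chains), catalog,
  mapping = read_residue_mapping(fx$files$mapping))
nets$protein
#> <interaction_network> granularity=protein: 2 nodes, 1 edges (1 core, 0 global)
#>   histone nodes: 1

network_stats(nets$protein, catalog)
#> nodes: 2
#> edges: 1 (core 1, global 0)
#> unique non-histone partners: 1

head(nets$residue$nodes, 3)
#>          id accession position is_histone
#> 1 P68431:11    P68431       11       TRUE
#> 2 P68431:12    P68431       12       TRUE
#> 3 P68431:13    P68431       13       TRUE
```

The fixture plants four contacts between an H3 chain (P68431) and one
partner; they collapse to a single protein-level edge whose evidence
item records 4 contacts, while the residue network keeps the four
interface residue pairs in UniProt coordinates (the fixture's mapping
offsets histone positions by +10, hence positions 11–15).

The same steps are available from a shell:

```sh
Rscript inst/cli/histonet.R make-fixtures --dir fx --seed 1 --profile minimal
Rscript inst/cli/histonet.R build-structural \
  --cif fx/minimal/FX01.cif --catalog fx/minimal/catalog.tsv \
  --mapping fx/minimal/mapping.tsv \
  --out-protein protein.graphml --out-residue residue.graphml
Rscript inst/cli/histonet.R stats --net protein.graphml
```

plus `build-crosslink`, `build-binary`, `domain-level`, `global`,
`merge` and `export` subcommands; run with no arguments for usage. All
outputs are byte-identical across reruns on the same inputs.

## Layout

* `R/` — data model and validation, mmCIF parsing, the three evidence
  sources, network operations, serialization, CLI, fixture generator
* `tests/testthat/` — unit, property and end-to-end tests (all fixtures
  generated in code)
* `vignettes/building-histone-interactomes.Rmd` — the methods notes:
  model, parameters, design decisions, limitations
* `inst/cli/histonet.R` — shell entry point
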