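---
title: "Building multi-evidence interactomes around histones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building multi-evidence interactomes around histones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histonet)
```

## The problem

Histones sit at the centre of chromatin regulation: readers, writers,
erasers, chaperones and remodellers all make physical contact with the
nucleosome or with free histones. No single experimental source captures
this interactome. Crystal and cryo-EM structures give atomic interfaces
but cover only complexes stable enough to solve; cross-linking mass
spectrometry (XL-MS) captures in-situ proximity between specific lysines
but only where tryptic peptides are observable; high-throughput binary
assays (yeast two-hybrid and relatives) scale to proteome level but give
no interface information at all.

`histonet` builds interaction networks around a focal protein family —
human histones in the shipped configuration, but the family is defined
entirely by a user-supplied catalog table — from these three evidence
kinds, at three levels of granularity (whole proteins, conserved-domain
families, individual residues), and integrates them into merged "global"
interactomes. Every edge carries its provenance as a list of evidence
items, so a merged network can always be decomposed back into its
sources.

An interaction, throughout the package, is a contact between a focal
histone and a **non-histone** protein. Histone–histone contacts (for
example H3–H4 within the octamer) are excluded uniformly across all
three sources, matching the interaction definition used for the
cross-linking and binary sources; this keeps the three core networks
comparable. The residue-level networks, which carry raw interface
geometry, are the place to look if intra-octamer contacts are ever
needed — the exclusion is applied at network construction, not at
contact extraction.

## The structural pipeline

The structural source starts from PDBx/mmCIF files of biological
assemblies and proceeds in four steps.

**Parsing and assembly expansion.** `parse_structure_cif()` reads the
`atom_site` table of the first data block, keeps polymer entities only,
drops waters, hydrogens and deuteriums, and resolves alternate
conformations to the highest-occupancy altloc (ties go to the conformer
first in the file). By default the first listed biological assembly is
expanded by applying its symmetry operators (`pdbx_struct_assembly_gen`
× `pdbx_struct_oper_list`, including composed operator products);
symmetry copies get a chain-id suffix so that crystallographic and
biological contacts stay distinguishable. Files without an assembly
definition fall back to the asymmetric unit with a warning. Residues are
identified by `label_asym_id`/`label_seq_id` throughout — the gap-free
numbering that SIFTS-style mapping tables key on — never by `auth_`
numbering. Modified residues (e.g. selenomethionine) are polymer
entities like any other and contribute their heavy atoms.

**Curation.** `apply_curation_filters()` applies three rules in a fixed
order, recording the first that fires: (i) structures with no catalog
histone chain of the focal species are excluded (`no_human_histone`);
(ii) structures whose candidate chains carry no protein accession at all
— synthetic constructs that cannot be mapped to any reference histone —
are excluded (`unmappable_synthetic`); (iii) structures with a focal
histone but no accession-mapped non-histone protein chain are excluded
(`no_partner`). Partner chains from other species are retained and
flagged rather than removed; a user-supplied conserved-partner map can
translate such accessions to their focal-proteome equivalents, and no
automatic orthology inference is attempted. A chain lacking an
accession cannot become a network node, so accession-less chains never
count as partners.

**Interface extraction.** Two residues are in contact when at least one
heavy atom of one is within the cutoff of a heavy atom of the other. The
default cutoff is 5.0 Å, and the comparison is inclusive (d ≤ cutoff) in
double precision with no tolerance padding: a pair at exactly 5.0 Å is a
contact, and results are bit-stable across runs. "Heavy atom" is
operationalised as any atom whose element is not H or D, so a structure
deposited with explicit hydrogens yields exactly the same contacts as
the same structure stripped of them. `extract_contacts()` computes
blockwise squared-distance matrices; the package also ships
`brute_force_contacts()`, a deliberately naive all-pairs double loop
kept free of any shared code with the fast path, which serves as the
oracle in the test suite.

**Mapping and network assembly.** Contacts are translated to
protein-sequence coordinates through a SIFTS-style table keyed on
(structure, chain, `label_seq_id`); contacts with any unmapped side are
partitioned into an `unmapped` set rather than silently dropped.
`build_structural_networks()` then collapses observations: the
protein-level network has one edge per unordered (histone, partner)
accession pair with one structural evidence item per contributing
structure (carrying the contact count and minimum distance), and the
residue-level network connects interface residues as
`accession:position` nodes.

## Cross-linking and binary sources

The XL-MS source consumes a table of inter-protein cross-links — two
accessions plus the 1-based positions of the bridged lysines, already in
protein-sequence coordinates (that mapping belongs to the upstream MS
pipeline and is trusted, not redone). Intra-protein links are dropped at
parse with a counted warning. A record observed in both fractionated and
unfractionated preparations collapses to a single record keeping both
fraction tags, so pooling the two sets cannot double-count an
interaction. Records with exactly one catalog-histone side become edges;
the residue-level network has one edge per record, a bijection the tests
assert. Whether one protein pair cross-linked at several distinct lysine
pairs counts as one interaction or several is a genuine ambiguity; the
package counts one protein-level edge per accession pair and leaves the
lysine-level multiplicity to the residue network.

The binary source consumes APID-style rows (two accessions, two taxa, a
set of detection-method codes). A row qualifies when at least one method
is in the configured binary set — the shipped default
(`default_binary_methods()`) covers two-hybrid variants, protein
complementation and far-western blotting, and is an editorial choice
documented as such, replaceable via config — and when both taxa equal
the focal taxon (inter-species rows are excluded, unlike the structural
source where cross-species complexes are genuine observations of
conserved binding). Only a protein-level network is built from this
source: binary assays provide no interface coordinates from which
domain- or residue-level networks could be derived.

## Granularity and layers

`to_domain_level()` groups non-histone partners by conserved-domain
family, unioning edge evidence; unannotated partners survive as
singleton pseudo-families named by their accession. A partner annotated
with several families maps, by default, to a single representative node:
the family overlapping its interface residues when a residue-level
network is supplied as a hint (most overlapping residues wins, ties
broken lexicographically), otherwise the first family in
annotation-table order. This single-node rule keeps the collapse
edge-count non-increasing, which we treat as the defining property of a
"grouping" operation; an `expand` mode maps multi-domain partners to
every annotated family instead, at the documented cost of that property.
Both modes are exposed because domain-level counts differ between them
and the difference is worth surfacing in `network_stats()` comparisons.

`expand_global()` adds one layer of partners-of-partners: each
neighbour-table pair anchored on a non-histone core node adds its other
endpoint and a `layer = "global"` edge. The expansion is strictly
one-hop — neighbours of neighbours are ignored, as are pairs touching
only histones or no core node — and never touches core elements. Each
evidence source keeps its own neighbour table; mixing across sources
happens only in `merge_networks()`, which unions nodes by normalized
accession (isoform suffixes are stripped, so isoforms of one entry
deduplicate to one node — coarser than isoform-aware identity, chosen
because accession-level deduplication is the convention in interactome
integration), unions edges by unordered pair, deduplicates evidence by
(kind, id), and refuses to mix granularities rather than coerce them.

## Determinism and numerical choices

All node and edge sets are sorted bytewise before serialization, no
output file contains wall-clock content, and every source of randomness
in the fixture generator flows from a single integer seed — so every
build, CLI run and fixture tree is byte-identical across repeats.
GraphML and JSON-graph exports are lossless (the test suite asserts
read∘write identity including evidence multisets); SIF and edge-TSV are
deliberately lossy views for Cytoscape-style consumption. Distances are
compared in double precision with no epsilon; the inclusive boundary
decision is pinned by a dedicated fixture that places an atom pair at
exactly the cutoff.

## What the synthetic fixtures do and do not show

`generate_fixture_suite()` produces toy complexes with CA/CB
pseudo-atoms and contacts planted at exact distances (kept ≥ 0.1 Å away
from the cutoff on both sides, except in the boundary profile), plus
small catalog, mapping, domain, cross-link, PPI and neighbour tables
whose expected outputs are computed inside the generator by independent
brute force. Test problem sizes are chosen to exercise every code path
at desk scale: random chains up to ~75 heavy atoms over 100 seeds for
the geometry oracle, 20 seeded toy networks for the algebra laws, and a
five-structure curation set covering every exclusion reason.

Passing these tests demonstrates the correctness of the geometry,
filtering, grouping and merging machinery — not the biological fidelity
of any real interactome. Real mmCIF files bring complications the
fixtures deliberately omit (insertion codes in `auth_` numbering, which
the package sidesteps by using `label_` numbering; micro-heterogeneity;
chimeric entities), and real evidence tables bring redundancy and error
the synthetic tables do not model. Published histone-interactome counts
are snapshots of living databases and are therefore not reproducible
from fixtures; they can be reproduced by pointing the same pipeline at
the corresponding downloaded tables.

## Known limitations

Nucleic-acid partners are out of scope (DNA-mediated proximity is not an
interaction here). Assembly operator expressions of the form `(A)(B)`
are supported as full Cartesian products applied right-to-left, but only
the first listed assembly is scanned by default — structures whose
relevant interface appears only in a later assembly need
`assembly_policy` handling per file. The conserved-partner map is a
user responsibility; no orthology is inferred. Cross-link records are
trusted as given: no FDR filtering or distance-restraint modelling is
applied.
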