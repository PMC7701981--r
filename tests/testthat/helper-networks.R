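# Shared test fixtures built in code.

toy_catalog <- function() {
  histone_catalog(c("P68431", "P62805", "P0C0S5"),
                  c("H3", "H4", "H2A"),
                  c("H3.1", "H4", "H2A.Z"))
}

# a small valid protein-level network: histone H linked to X and Y
toy_protein_network <- function() {
  nodes <- data.frame(id = c("P68431", "Q00001", "Q00002"),
                      name = c("H3.1", "X", "Y"),
                      species_taxon = 9606L,
                      is_histone = c(TRUE, FALSE, FALSE),
                      stringsAsFactors = FALSE)
  edges <- data.frame(node_a = c("P68431", "P68431"),
                      node_b = c("Q00001", "Q00002"),
                      stringsAsFactors = FALSE)
  edges$evidence <- I(list(list(evidence_item("structural", "1ABC")),
                           list(evidence_item("crosslink", "XL1"))))
  interaction_network(nodes, edges, "protein")
}

# chain record with a single CA atom per given position
point_chain <- function(chain_id, accession, coords,
                        structure_id = "TST", taxon = 9606L,
                        elements = NULL) {
  n <- nrow(coords)
  atoms <- data.frame(seq_pos = coords$seq_pos,
                      residue_name = "ALA",
                      atom_name = paste0("A", seq_len(n)),
                      element = if (is.null(elements)) rep("C", n)
                                else elements,
                      x = coords$x, y = coords$y, z = coords$z,
                      stringsAsFactors = FALSE)
  list(structure_id = structure_id, chain_id = chain_id, entity_id = "1",
       accession = accession, species_taxon = taxon, atoms = atoms)
}
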