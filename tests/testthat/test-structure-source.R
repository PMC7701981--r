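# mmCIF parsing, curation, contact extraction, residue mapping.

test_that("toy mmCIF parses to polymer chains without waters or hydrogens", {
  d <- withr::local_tempdir()
  man <- generate_fixture_suite(1, "minimal", d)
  chains <- parse_structure_cif(man$files$cif)
  expect_length(chains, 2L)
  expect_equal(vapply(chains, `[[`, character(1), "chain_id"), c("A", "B"))
  expect_equal(vapply(chains, `[[`, character(1), "accession"),
               c("P68431", "Q9FIX1"))
  expect_equal(vapply(chains, `[[`, integer(1), "species_taxon"),
               c(9606L, 9606L))
  # chain A: 8 CA atoms; chain B: 6 CA atoms, planted hydrogen dropped,
  # the water never becomes a chain
  expect_equal(nrow(chains[[1]]$atoms), 8L)
  expect_equal(nrow(chains[[2]]$atoms), 6L)
  expect_false(any(chains[[2]]$atoms$element %in% c("H", "D")))
  # seq positions strictly increasing within each chain's residue order
  for (ch in chains)
    expect_true(all(diff(unique(ch$atoms$seq_pos)) > 0))
})

test_that("mmCIF with zero polymer entities parses to an empty chain list", {
  cif <- c("data_EMPTY",
           "_entry.id EMPTY",
           "loop_", "_entity.id", "_entity.type", "9 water",
           "loop_",
           "_atom_site.group_PDB", "_atom_site.id",
           "_atom_site.type_symbol", "_atom_site.label_atom_id",
           "_atom_site.label_alt_id", "_atom_site.label_comp_id",
           "_atom_site.label_asym_id", "_atom_site.label_entity_id",
           "_atom_site.label_seq_id", "_atom_site.Cartn_x",
           "_atom_site.Cartn_y", "_atom_site.Cartn_z",
           "_atom_site.occupancy",
           "HETATM 1 O O . HOH W 9 . 1.0 1.0 1.0 1.00")
  expect_length(suppressWarnings(parse_structure_cif(cif)), 0L)
})

test_that("malformed mmCIF names the offending block", {
  expect_error(parse_structure_cif(c("data_X", "_entry.id X")),
               "atom_site")
  bad_loop <- c("data_X", "loop_", "_atom_site.id", "_atom_site.Cartn_x",
                "1 2 3")  # 3 values for 2 columns
  expect_error(parse_structure_cif(bad_loop), "atom_site")
})

test_that("a 2-fold assembly operator yields two transformed chain copies", {
  d <- withr::local_tempdir()
  pos <- data.frame(seq_pos = 1:2, x = c(1, 2), y = c(0, 0), z = c(3, 4))
  rot2 <- list(R = matrix(c(-1, 0, 0, 0, -1, 0, 0, 0, 1), 3, byrow = TRUE),
               t = c(10, 0, 0))  # 2-fold about z then translate
  f <- file.path(d, "sym.cif")
  histonet:::write_toy_cif("SYM1", list(
    histonet:::ca_chain("A", "1", "P68431", 9606L, pos)), f,
    assembly = list(oper = list(list(R = diag(3), t = c(0, 0, 0)), rot2),
                    asym_ids = "A"))
  chains <- parse_structure_cif(f, "first_assembly")
  expect_length(chains, 2L)
  expect_equal(chains[[1]]$chain_id, "A")
  expect_equal(chains[[2]]$chain_id, "A-2")
  # hand-applied operator: (x,y,z) -> (-x+10, -y, z)
  expect_equal(chains[[2]]$atoms$x, c(-1 + 10, -2 + 10))
  expect_equal(chains[[2]]$atoms$y, c(0, 0))
  expect_equal(chains[[2]]$atoms$z, c(3, 4))
})

test_that("first_assembly without assembly categories warns and falls back", {
  cif <- c("data_NOASM", "_entry.id NOASM",
           "loop_", "_entity.id", "_entity.type", "1 polymer",
           "loop_",
           "_atom_site.group_PDB", "_atom_site.id",
           "_atom_site.type_symbol", "_atom_site.label_atom_id",
           "_atom_site.label_alt_id", "_atom_site.label_comp_id",
           "_atom_site.label_asym_id", "_atom_site.label_entity_id",
           "_atom_site.label_seq_id", "_atom_site.Cartn_x",
           "_atom_site.Cartn_y", "_atom_site.Cartn_z",
           "_atom_site.occupancy",
           "ATOM 1 C CA . ALA A 1 1 0.0 0.0 0.0 1.00")
  expect_warning(chains <- parse_structure_cif(cif, "first_assembly"),
                 "asymmetric unit")
  expect_length(chains, 1L)
  # asking for the asymmetric unit directly is silent
  expect_silent(parse_structure_cif(cif, "asymmetric_unit"))
})

test_that("alternate locations resolve to highest occupancy, ties to first", {
  hdr <- c("data_ALT", "_entry.id ALT",
           "loop_", "_entity.id", "_entity.type", "1 polymer",
           "loop_",
           "_atom_site.group_PDB", "_atom_site.id",
           "_atom_site.type_symbol", "_atom_site.label_atom_id",
           "_atom_site.label_alt_id", "_atom_site.label_comp_id",
           "_atom_site.label_asym_id", "_atom_site.label_entity_id",
           "_atom_site.label_seq_id", "_atom_site.Cartn_x",
           "_atom_site.Cartn_y", "_atom_site.Cartn_z",
           "_atom_site.occupancy")
  cif <- c(hdr,
           "ATOM 1 C CA A ALA A 1 1 1.0 0.0 0.0 0.40",
           "ATOM 2 C CA B ALA A 1 1 2.0 0.0 0.0 0.60",
           "ATOM 3 C CB A ALA A 1 1 3.0 0.0 0.0 0.50",
           "ATOM 4 C CB B ALA A 1 1 4.0 0.0 0.0 0.50")
  chains <- suppressWarnings(parse_structure_cif(cif))
  at <- chains[[1]]$atoms
  expect_equal(nrow(at), 2L)
  expect_equal(at$x[at$atom_name == "CA"], 2.0)  # occupancy 0.6 wins
  expect_equal(at$x[at$atom_name == "CB"], 3.0)  # tie -> first in file
})

test_that("contact extraction matches the planted minimal fixture", {
  d <- withr::local_tempdir()
  man <- generate_fixture_suite(5, "minimal", d)
  chains <- parse_structure_cif(man$files$cif)
  ct <- extract_contacts(chains[[1]], chains[[2]], cutoff = man$cutoff)
  expect_equal(nrow(ct), man$expected$n_contacts)
  expect_equal(ct$histone_seq_pos,
               man$expected$contact_pairs$histone_seq_pos)
  expect_equal(ct$partner_seq_pos,
               man$expected$contact_pairs$partner_seq_pos)
  expect_equal(ct$min_distance, man$expected$contact_min_distances,
               tolerance = 1e-12)
  expect_true(all(ct$min_distance <= man$cutoff))
})

test_that("chains far apart yield no contacts; hydrogens never count", {
  a <- point_chain("A", "P68431", data.frame(seq_pos = 1, x = 0, y = 0,
                                             z = 0))
  b_far <- point_chain("B", "Q1", data.frame(seq_pos = 1, x = 100, y = 0,
                                             z = 0))
  expect_equal(nrow(extract_contacts(a, b_far, 5)), 0L)
  # CA at 4.9 A plus a hydrogen 3.0 A in between: one contact at 4.9
  b <- point_chain("B", "Q1",
                   data.frame(seq_pos = c(1, 1), x = c(4.9, 3.0), y = 0,
                              z = 0), elements = c("C", "H"))
  ct <- extract_contacts(a, b, 5)
  expect_equal(nrow(ct), 1L)
  expect_equal(ct$min_distance, 4.9)
  # a chain of only hydrogens has zero heavy atoms
  b_h <- point_chain("B", "Q1", data.frame(seq_pos = 1, x = 1, y = 0,
                                           z = 0), elements = "H")
  expect_warning(ct2 <- extract_contacts(a, b_h, 5), "zero heavy atoms")
  expect_equal(nrow(ct2), 0L)
})

test_that("the distance rule is inclusive at the cutoff boundary", {
  d <- withr::local_tempdir()
  man <- generate_fixture_suite(2, "boundary", d)
  chains <- parse_structure_cif(man$files$cif)
  ct <- extract_contacts(chains[[1]], chains[[2]], cutoff = man$cutoff)
  expect_equal(nrow(ct), man$expected$n_contacts_inclusive)
  expect_equal(ct$min_distance, man$expected$boundary_distance)
  # the pair 0.1 A outside the cutoff is absent
  expect_false(any(ct$histone_seq_pos == 2))
})

test_that("contacts match the brute-force oracle on random chains", {
  for (seed in 1:20) {
    a <- random_chain(seed, n_res = 15, box = 25, chain_id = "A")
    b <- random_chain(seed + 1000, n_res = 15, box = 25, chain_id = "B")
    got <- extract_contacts(a, b, 5)
    want <- brute_force_contacts(a, b, 5)
    expect_equal(got$histone_seq_pos, want$histone_seq_pos)
    expect_equal(got$partner_seq_pos, want$partner_seq_pos)
    expect_equal(got$min_distance, want$min_distance, tolerance = 1e-12)
  }
})

test_that("contact sets are monotone in the cutoff and symmetric", {
  pair_key <- function(ct) paste(ct$histone_seq_pos, ct$partner_seq_pos)
  for (seed in 1:10) {
    a <- random_chain(seed, n_res = 12, box = 20, chain_id = "A")
    b <- random_chain(seed + 500, n_res = 12, box = 20, chain_id = "B")
    c1 <- extract_contacts(a, b, 3.5)
    c2 <- extract_contacts(a, b, 5.0)
    c3 <- extract_contacts(a, b, 8.0)
    expect_true(all(pair_key(c1) %in% pair_key(c2)))
    expect_true(all(pair_key(c2) %in% pair_key(c3)))
    # mirror image with identical minimum distances
    m <- extract_contacts(b, a, 5.0)
    expect_setequal(paste(m$partner_seq_pos, m$histone_seq_pos,
                          m$min_distance),
                    paste(c2$histone_seq_pos, c2$partner_seq_pos,
                          c2$min_distance))
  }
})

test_that("curation classifies the five-structure fixture exactly", {
  d <- withr::local_tempdir()
  man <- generate_fixture_suite(4, "curation", d)
  catalog <- read_histone_catalog(man$files$catalog)
  cifs <- man$files[grepl("^CU", names(man$files))]
  structures <- lapply(cifs, function(f)
    suppressWarnings(parse_structure_cif(f)))
  names(structures) <- names(cifs)
  rep <- apply_curation_filters(structures, catalog, 9606L)
  expect_setequal(rep$retained, man$expected$retained)
  got_exc <- rep$excluded[order(rep$excluded$structure_id), ]
  rownames(got_exc) <- NULL
  expect_equal(got_exc, man$expected$excluded)
  # partition: retained and excluded disjoint, union = input
  expect_length(intersect(rep$retained, rep$excluded$structure_id), 0L)
  expect_setequal(c(rep$retained, rep$excluded$structure_id),
                  names(structures))
  # the inter-species partner is flagged, not removed
  expect_true(man$expected$flagged_interspecies %in%
                rep$flagged_interspecies$structure_id)
})

test_that("curation handles empty input and single-category examples", {
  catalog <- toy_catalog()
  rep <- apply_curation_filters(list(), catalog)
  expect_length(rep$retained, 0L)
  expect_equal(nrow(rep$excluded), 0L)
  near <- data.frame(seq_pos = 1:2, x = c(0, 6), y = 0, z = 0)
  hist_mouse <- point_chain("A", "P68431", near, taxon = 10090L)
  partner <- point_chain("B", "Q99999", near)
  hist_human <- point_chain("A", "P68431", near)
  r1 <- apply_curation_filters(list(S1 = list(hist_mouse, partner)),
                               catalog)
  expect_equal(r1$excluded$reason, "no_human_histone")
  r2 <- apply_curation_filters(list(S2 = list(hist_human)), catalog)
  expect_equal(r2$excluded$reason, "no_partner")
})

test_that("residue mapping translates and partitions contacts", {
  contacts <- data.frame(structure_id = "TST", histone_chain = "A",
                         histone_seq_pos = c(1L, 2L),
                         histone_residue = "ALA", partner_chain = "B",
                         partner_seq_pos = c(1L, 9L),
                         partner_residue = "ALA",
                         min_distance = c(3.0, 4.0),
                         stringsAsFactors = FALSE)
  mapping <- data.frame(
    structure_id = "TST", chain_id = c("A", "A", "B"),
    seq_pos = c(1L, 2L, 1L),
    accession = c("P68431", "P68431", "Q00001"),
    uniprot_pos = c(25L, 26L, 101L), stringsAsFactors = FALSE)
  res <- map_contacts_to_uniprot(contacts, mapping)
  # row 1 fully mapped with the documented single-row lookup semantics
  expect_equal(nrow(res$mapped), 1L)
  expect_equal(res$mapped$histone_uniprot_pos, 25L)
  expect_equal(res$mapped$partner_uniprot_pos, 101L)
  # row 2's partner residue 9 has no mapping row -> unmapped, not dropped
  expect_equal(nrow(res$unmapped), 1L)
  expect_equal(res$unmapped$partner_seq_pos, 9L)

  # identity mapping passes positions through
  id_map <- data.frame(structure_id = "TST",
                       chain_id = c("A", "A", "B", "B"),
                       seq_pos = c(1L, 2L, 1L, 9L),
                       accession = c("P68431", "P68431", "Q00001",
                                     "Q00001"),
                       uniprot_pos = c(1L, 2L, 1L, 9L),
                       stringsAsFactors = FALSE)
  res2 <- map_contacts_to_uniprot(contacts, id_map)
  expect_equal(res2$mapped$histone_uniprot_pos,
               contacts$histone_seq_pos)
  expect_equal(res2$mapped$partner_uniprot_pos,
               contacts$partner_seq_pos)
})

test_that("structural networks collapse contacts per accession pair", {
  catalog <- toy_catalog()
  near <- data.frame(seq_pos = 1:4, x = 6 * (1:4), y = 0, z = 0)
  touch <- data.frame(seq_pos = 1:4, x = 6 * (1:4), y = 4, z = 0)
  mk <- function(sid) list(point_chain("A", "P68431", near,
                                       structure_id = sid),
                           point_chain("B", "Q00001", touch,
                                       structure_id = sid))
  # one structure with 4 contact pairs -> 2 nodes, 1 edge, 1 evidence item
  nets <- build_structural_networks(list(S1 = mk("S1")), catalog)
  expect_equal(nrow(nets$protein$nodes), 2L)
  expect_equal(nrow(nets$protein$edges), 1L)
  expect_length(nets$protein$evidence[[1]], 1L)
  expect_equal(nets$protein$evidence[[1]][[1]]$attributes$n_contacts, 4)
  # same pair in 3 structures -> still 1 edge, 3 evidence items
  nets3 <- build_structural_networks(
    list(S1 = mk("S1"), S2 = mk("S2"), S3 = mk("S3")), catalog)
  expect_equal(nrow(nets3$protein$edges), 1L)
  expect_length(nets3$protein$evidence[[1]], 3L)
  expect_setequal(vapply(nets3$protein$evidence[[1]], `[[`, character(1),
                         "source_id"), c("S1", "S2", "S3"))
  # residue-level network carries accession:position nodes, all validated
  expect_equal(nets$residue$granularity, "residue")
  expect_equal(nrow(validate_network(nets$residue, catalog)), 0L)
  expect_equal(nrow(validate_network(nets3$protein, catalog)), 0L)
  # no structures -> empty networks with a warning
  expect_warning(empty <- build_structural_networks(list(), catalog),
                 "no retained structures")
  expect_equal(nrow(empty$protein$edges), 0L)
})

test_that("conserved-partner translation renames other-species partners", {
  catalog <- toy_catalog()
  near <- data.frame(seq_pos = 1:2, x = c(0, 6), y = 0, z = 0)
  touch <- data.frame(seq_pos = 1:2, x = c(0, 6), y = 4, z = 0)
  st <- list(S1 = list(point_chain("A", "P68431", near),
                       point_chain("B", "MOUSE1", touch, taxon = 10090L)))
  nets <- build_structural_networks(
    st, catalog, conserved_map = c(MOUSE1 = "Q11111"))
  expect_true("Q11111" %in% nets$protein$nodes$id)
  expect_false("MOUSE1" %in% nets$protein$nodes$id)
})

test_that("interface BED export merges adjacent residue positions", {
  d <- withr::local_tempdir()
  man <- generate_fixture_suite(1, "minimal", d)
  catalog <- read_histone_catalog(man$files$catalog)
  chains <- parse_structure_cif(man$files$cif)
  nets <- build_structural_networks(
    list(FX01 = chains), catalog,
    mapping = read_residue_mapping(man$files$mapping))
  bed <- write_interface_bed(nets$residue, file.path(d, "iface.tsv"))
  # histone interface 11,12,13,15 -> intervals [11,13] and [15,15]
  hseg <- bed[bed$accession == "P68431", ]
  expect_equal(hseg$start, c(11L, 15L))
  expect_equal(hseg$end, c(13L, 15L))
  expect_true(file.exists(file.path(d, "iface.tsv")))
})
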