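# Deterministic synthetic-input generator. Every pipeline stage can be
# exercised offline: toy mmCIF complexes with contacts planted at exact
# distances, histone catalogs, SIFTS-style residue mappings, domain
# tables, cross-link and PPI tables. Expected outputs in the manifest
# are computed by plain brute force inside this module, independently of
# the builder code, so fixture tests are oracle comparisons.
#
# Planted contact distances stay at least 0.1 Angstrom away from the
# cutoff on either side (no boundary ambiguity); the dedicated
# `boundary` profile pins an atom pair at exactly the cutoff to fix the
# inclusive (d <= cutoff) reading of "within".

#' Brute-force residue contact oracle
#'
#' Reference implementation of contact extraction: a literal double loop
#' over all heavy-atom pairs with no blocking, used to compute
#' expected values for fixtures and as the independent oracle in tests.
#'
#' @param histone_chain,partner_chain chain records (as from
#'   [parse_structure_cif()]).
#' @param cutoff distance cutoff in Angstrom.
#' @return data frame `histone_seq_pos`, `partner_seq_pos`,
#'   `min_distance`, sorted by the two positions.
#' @export
brute_force_contacts <- function(histone_chain, partner_chain,
                                 cutoff = 5.0) {
  ha <- histone_chain$atoms
  pa <- partner_chain$atoms
  ha <- ha[!ha$element %in% c("H", "D"), , drop = FALSE]
  pa <- pa[!pa$element %in% c("H", "D"), , drop = FALSE]
  res <- list()
  for (hp in unique(ha$seq_pos)) {
    hx <- ha[ha$seq_pos == hp, , drop = FALSE]
    for (pp in unique(pa$seq_pos)) {
      px <- pa[pa$seq_pos == pp, , drop = FALSE]
      best <- Inf
      for (i in seq_len(nrow(hx))) for (j in seq_len(nrow(px))) {
        d <- sqrt((hx$x[i] - px$x[j])^2 + (hx$y[i] - px$y[j])^2 +
                    (hx$z[i] - px$z[j])^2)
        if (d < best) best <- d
      }
      if (best <= cutoff)
        res[[length(res) + 1L]] <- data.frame(
          histone_seq_pos = hp, partner_seq_pos = pp, min_distance = best)
    }
  }
  out <- if (length(res)) do.call(rbind, res)
         else data.frame(histone_seq_pos = integer(),
                         partner_seq_pos = integer(),
                         min_distance = numeric())
  out <- out[order(out$histone_seq_pos, out$partner_seq_pos), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Random toy chain record
#'
#' A synthetic protein chain with 1-3 heavy pseudo-atoms (CA/CB/CG) per
#' residue, coordinates uniform in a cube and rounded to 3 decimals.
#' Used for randomized contact-geometry tests.
#'
#' @param seed integer seed.
#' @param n_res number of residues.
#' @param box edge length of the coordinate cube in Angstrom.
#' @param chain_id,structure_id,accession,taxon identity fields.
#' @return a chain record.
#' @export
random_chain <- function(seed, n_res = 20, box = 30,
                         chain_id = "A", structure_id = "RND",
                         accession = NA_character_, taxon = NA_integer_) {
  set.seed(seed)
  atoms <- list()
  names3 <- c("CA", "CB", "CG")
  for (r in seq_len(n_res)) {
    k <- sample.int(3L, 1L)
    for (j in seq_len(k)) {
      atoms[[length(atoms) + 1L]] <- data.frame(
        seq_pos = r, residue_name = "ALA", atom_name = names3[j],
        element = "C",
        x = round(stats::runif(1, 0, box), 3),
        y = round(stats::runif(1, 0, box), 3),
        z = round(stats::runif(1, 0, box), 3),
        stringsAsFactors = FALSE)
    }
  }
  list(structure_id = structure_id, chain_id = chain_id, entity_id = "1",
       accession = accession, species_taxon = taxon,
       atoms = do.call(rbind, atoms))
}

#' Random toy protein-level network
#'
#' A small histone-centred network with `n_hist` histone hubs and
#' `n_partners` partners, each partner linked to one or more random
#' histones, with one synthetic evidence item per edge. Used for
#' network-algebra property tests.
#'
#' @param seed integer seed.
#' @param n_hist number of histone nodes (1-4).
#' @param n_partners number of partner nodes.
#' @param source_kind evidence kind of the synthetic items.
#' @return a protein-level [interaction_network()].
#' @export
random_toy_network <- function(seed, n_hist = 2, n_partners = 6,
                               source_kind = "structural") {
  set.seed(seed)
  hist_pool <- c("P68431", "P62805", "P0C0S5", "P06899")
  hist_acc <- hist_pool[seq_len(min(n_hist, length(hist_pool)))]
  partners <- sprintf("Q%05d", sample.int(99999L, n_partners))
  edges <- list()
  for (p in partners) {
    for (h in hist_acc[stats::runif(length(hist_acc)) < 0.6 |
                         seq_along(hist_acc) == 1]) {
      edges[[length(edges) + 1L]] <- c(h, p)
    }
  }
  em <- do.call(rbind, edges)
  node_df <- data.frame(id = c(hist_acc, partners),
                        name = c(hist_acc, partners),
                        species_taxon = 9606L,
                        is_histone = c(rep(TRUE, length(hist_acc)),
                                       rep(FALSE, length(partners))),
                        stringsAsFactors = FALSE)
  edge_df <- data.frame(node_a = em[, 1], node_b = em[, 2],
                        stringsAsFactors = FALSE)
  edge_df$evidence <- I(lapply(seq_len(nrow(em)), function(i)
    list(evidence_item(source_kind, sprintf("ev%04d", i)))))
  interaction_network(node_df, edge_df, "protein",
                      provenance = list(source = source_kind,
                                        fixture_seed = seed))
}

# ---- mmCIF writing ------------------------------------------------------

fmt_atom_row <- function(serial, group, atom_name, element, comp, asym,
                         entity, seq_pos, x, y, z, occ = 1.0, alt = ".") {
  sprintf("%s %d %s %s %s %s %s %s %d %.3f %.3f %.3f %.2f",
          group, serial, element, atom_name, alt, comp, asym, entity,
          seq_pos, x, y, z, occ)
}

# chains: list of list(asym, entity, accession (NA ok), taxon (NA ok),
#                      atoms = data.frame(seq_pos, residue_name,
#                      atom_name, element, x, y, z, occupancy?, alt?),
#                      polymer = TRUE)
# assembly: NULL, or list(oper = list of list(R, t), asym_ids)
write_toy_cif <- function(structure_id, chains, path, assembly = NULL,
                          extra_waters = 0L) {
  lines <- c(sprintf("data_%s", structure_id),
             "#",
             sprintf("_entry.id %s", structure_id),
             "#",
             "loop_",
             "_entity.id",
             "_entity.type")
  ents <- unique(vapply(chains, `[[`, character(1), "entity"))
  for (e in ents) {
    poly <- any(vapply(chains, function(ch)
      ch$entity == e && isTRUE(ch$polymer %||% TRUE), logical(1)))
    lines <- c(lines, sprintf("%s %s", e, if (poly) "polymer" else "water"))
  }
  lines <- c(lines, "#")

  refs <- Filter(function(ch) !is.na(ch$accession %||% NA_character_),
                 chains)
  if (length(refs)) {
    lines <- c(lines, "loop_", "_struct_ref.id", "_struct_ref.db_name",
               "_struct_ref.entity_id", "_struct_ref.pdbx_db_accession")
    seen <- character()
    i <- 0L
    for (ch in refs) {
      if (ch$entity %in% seen) next
      seen <- c(seen, ch$entity)
      i <- i + 1L
      lines <- c(lines, sprintf("%d UNP %s %s", i, ch$entity,
                                ch$accession))
    }
    lines <- c(lines, "#")
  }
  src <- Filter(function(ch) !is.na(ch$taxon %||% NA_integer_), chains)
  if (length(src)) {
    lines <- c(lines, "loop_", "_entity_src_gen.entity_id",
               "_entity_src_gen.pdbx_gene_src_ncbi_taxonomy_id")
    seen <- character()
    for (ch in src) {
      if (ch$entity %in% seen) next
      seen <- c(seen, ch$entity)
      lines <- c(lines, sprintf("%s %d", ch$entity, ch$taxon))
    }
    lines <- c(lines, "#")
  }

  if (!is.null(assembly)) {
    lines <- c(lines,
      "_pdbx_struct_assembly.id 1",
      sprintf("_pdbx_struct_assembly.oligomeric_count %d",
              length(assembly$oper)),
      "#",
      "loop_", "_pdbx_struct_assembly_gen.assembly_id",
      "_pdbx_struct_assembly_gen.oper_expression",
      "_pdbx_struct_assembly_gen.asym_id_list",
      sprintf("1 %s %s",
              paste(seq_along(assembly$oper), collapse = ","),
              paste(assembly$asym_ids, collapse = ",")),
      "#",
      "loop_", "_pdbx_struct_oper_list.id",
      "_pdbx_struct_oper_list.type",
      "_pdbx_struct_oper_list.matrix[1][1]",
      "_pdbx_struct_oper_list.matrix[1][2]",
      "_pdbx_struct_oper_list.matrix[1][3]",
      "_pdbx_struct_oper_list.vector[1]",
      "_pdbx_struct_oper_list.matrix[2][1]",
      "_pdbx_struct_oper_list.matrix[2][2]",
      "_pdbx_struct_oper_list.matrix[2][3]",
      "_pdbx_struct_oper_list.vector[2]",
      "_pdbx_struct_oper_list.matrix[3][1]",
      "_pdbx_struct_oper_list.matrix[3][2]",
      "_pdbx_struct_oper_list.matrix[3][3]",
      "_pdbx_struct_oper_list.vector[3]")
    for (i in seq_along(assembly$oper)) {
      op <- assembly$oper[[i]]
      typ <- if (all(op$R == diag(3)) && all(op$t == 0))
        "'identity operation'" else "'crystal symmetry operation'"
      lines <- c(lines, sprintf(
        "%d %s %g %g %g %g %g %g %g %g %g %g %g %g",
        i, typ,
        op$R[1, 1], op$R[1, 2], op$R[1, 3], op$t[1],
        op$R[2, 1], op$R[2, 2], op$R[2, 3], op$t[2],
        op$R[3, 1], op$R[3, 2], op$R[3, 3], op$t[3]))
    }
    lines <- c(lines, "#")
  }

  lines <- c(lines, "loop_",
             "_atom_site.group_PDB", "_atom_site.id",
             "_atom_site.type_symbol", "_atom_site.label_atom_id",
             "_atom_site.label_alt_id", "_atom_site.label_comp_id",
             "_atom_site.label_asym_id", "_atom_site.label_entity_id",
             "_atom_site.label_seq_id", "_atom_site.Cartn_x",
             "_atom_site.Cartn_y", "_atom_site.Cartn_z",
             "_atom_site.occupancy")
  serial <- 0L
  for (ch in chains) {
    at <- ch$atoms
    for (i in seq_len(nrow(at))) {
      serial <- serial + 1L
      occ <- if ("occupancy" %in% names(at)) at$occupancy[i] else 1.0
      alt <- if ("alt" %in% names(at)) at$alt[i] else "."
      lines <- c(lines, fmt_atom_row(
        serial, "ATOM", at$atom_name[i], at$element[i],
        at$residue_name[i], ch$asym, ch$entity, at$seq_pos[i],
        at$x[i], at$y[i], at$z[i], occ, alt))
    }
  }
  for (w in seq_len(extra_waters)) {
    serial <- serial + 1L
    lines <- c(lines, sprintf(
      "HETATM %d O O . HOH W %s . %.3f %.3f %.3f 1.00",
      serial, "9", 90 + w, 90, 90))
  }
  lines <- c(lines, "#")
  writeLines(lines, path)
  invisible(path)
}

# simple CA-only chain builder: positions is data.frame(seq_pos,x,y,z)
ca_chain <- function(asym, entity, accession, taxon, positions,
                     extra_atoms = NULL) {
  atoms <- data.frame(seq_pos = positions$seq_pos, residue_name = "ALA",
                      atom_name = "CA", element = "C",
                      x = positions$x, y = positions$y, z = positions$z,
                      stringsAsFactors = FALSE)
  if (!is.null(extra_atoms)) atoms <- rbind(atoms, extra_atoms)
  atoms <- atoms[order(atoms$seq_pos), , drop = FALSE]
  list(asym = asym, entity = entity, accession = accession, taxon = taxon,
       atoms = atoms, polymer = TRUE)
}

default_fixture_catalog <- function() {
  data.frame(
    accession = c("P68431", "P62805", "P0C0S5", "P06899"),
    family = c("H3", "H4", "H2A", "H2B"),
    variant = c("H3.1", "H4", "H2A.Z", "H2B1J"),
    taxon = 9606L, stringsAsFactors = FALSE)
}

#' Generate a synthetic fixture suite
#'
#' Writes a self-contained set of toy inputs under `dir` and returns a
#' manifest whose `expected` entries were computed by independent brute
#' force over the planted data (never by the builder functions). The
#' same seed always reproduces byte-identical files.
#'
#' Profiles: `minimal` - one two-chain complex with 4 planted contacts
#' (plus a decoy hydrogen inside the cutoff and a water), all evidence
#' tables and a non-identity residue mapping; `curation` - five
#' structures covering the three exclusion reasons plus two retainable
#' ones; `boundary` - an atom pair at exactly the cutoff and one just
#' outside; `merge` - two overlapping toy protein networks plus their
#' hand-enumerated union counts.
#'
#' @param seed integer seed.
#' @param profile `"minimal"`, `"curation"`, `"boundary"` or `"merge"`.
#' @param dir output directory (created if needed).
#' @param cutoff contact cutoff the fixture is planted against
#'   (default 5.0).
#' @return the manifest: list with `seed`, `profile`, `dir`, `files`
#'   (named paths) and `expected` (stage-wise expected values).
#' @export
generate_fixture_suite <- function(seed, profile = c("minimal", "curation",
                                                     "boundary", "merge"),
                                   dir, cutoff = 5.0) {
  profile <- match.arg(profile)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  switch(profile,
         minimal = fixture_minimal(seed, dir, cutoff),
         curation = fixture_curation(seed, dir),
         boundary = fixture_boundary(seed, dir, cutoff),
         merge = fixture_merge(seed, dir))
}

fixture_minimal <- function(seed, dir, cutoff) {
  set.seed(seed)
  files <- list()
  # histone chain A (H3, P68431): 8 residues on a line, 6 A apart
  hist_pos <- data.frame(seq_pos = 1:8, x = 6 * (1:8), y = 0, z = 0)
  # partner chain B: 6 residues, far row at y = 40
  part_pos <- data.frame(seq_pos = 1:6, x = 6 * (1:6), y = 40, z = 0)
  # plant 4 contacts: partner residues moved next to histone residues
  planted <- data.frame(
    h = c(1L, 2L, 3L, 5L), p = c(1L, 2L, 3L, 5L),
    d = c(3.0, 4.0, 4.5, 4.9))
  for (i in seq_len(nrow(planted))) {
    part_pos$x[planted$p[i]] <- 6 * planted$h[i]
    part_pos$y[planted$p[i]] <- planted$d[i]
  }
  # decoy hydrogen on partner residue 6, 2 A from histone residue 7 CA;
  # ignored by the heavy-atom rule (its residue's CA stays far away)
  decoy_h <- data.frame(seq_pos = 6L, residue_name = "ALA",
                        atom_name = "H1", element = "H",
                        x = 6 * 7, y = 2.0, z = 0,
                        stringsAsFactors = FALSE)
  chain_h <- ca_chain("A", "1", "P68431", 9606L, hist_pos)
  chain_p <- ca_chain("B", "2", "Q9FIX1", 9606L, part_pos,
                      extra_atoms = decoy_h)
  cif <- file.path(dir, "FX01.cif")
  write_toy_cif("FX01", list(chain_h, chain_p), cif,
                assembly = list(
                  oper = list(list(R = diag(3), t = c(0, 0, 0))),
                  asym_ids = c("A", "B")),
                extra_waters = 1L)
  files$cif <- cif

  catalog <- default_fixture_catalog()
  files$catalog <- file.path(dir, "catalog.tsv")
  write_tsv_plain(catalog, files$catalog)

  # non-identity residue mapping: histone offset +10, partner offset +100
  map <- rbind(
    data.frame(structure_id = "FX01", chain_id = "A",
               seq_pos = hist_pos$seq_pos, accession = "P68431",
               uniprot_pos = hist_pos$seq_pos + 10L,
               stringsAsFactors = FALSE),
    data.frame(structure_id = "FX01", chain_id = "B",
               seq_pos = part_pos$seq_pos, accession = "Q9FIX1",
               uniprot_pos = part_pos$seq_pos + 100L,
               stringsAsFactors = FALSE))
  files$mapping <- file.path(dir, "mapping.tsv")
  write_tsv_plain(map, files$mapping)

  # domain annotations: partner Q9FIX1 and a second protein share family
  domains <- data.frame(
    accession = c("Q9FIX1", "Q8OTHR", "Q9FIX1"),
    family_id = c("FAM001", "FAM001", "FAM002"),
    family_name = c("toy-bromo", "toy-bromo", "toy-chromo"),
    start = c(95L, 1L, 140L), end = c(130L, 60L, 180L),
    stringsAsFactors = FALSE)
  files$domains <- file.path(dir, "domains.tsv")
  write_tsv_plain(domains, files$domains)

  # cross-link table: 6 rows -> 4 qualifying inter-protein histone links
  # (one intra dropped, one histone-histone dropped, one duplicate pair
  # across fractions collapses)
  xl <- data.frame(
    accession_a = c("P68431", "P68431", "P62805", "P68431", "P68431",
                    "Q7XLNK"),
    pos_a = c(24L, 24L, 32L, 57L, 18L, 5L),
    accession_b = c("Q7XLNK", "Q7XLNK", "Q7XLNK", "Q8OTHR", "P62805",
                    "Q7XLNK"),
    pos_b = c(88L, 88L, 101L, 12L, 45L, 9L),
    fraction = c("fractionated", "unfractionated", "fractionated",
                 "unfractionated", "fractionated", "fractionated"),
    record_id = sprintf("XL%03d", 1:6), stringsAsFactors = FALSE)
  files$crosslinks <- file.path(dir, "crosslinks.tsv")
  write_tsv_plain(xl, files$crosslinks)

  # PPI table: 5 rows -> 2 qualifying (one non-binary method, one
  # inter-species, one histone-histone)
  ppi <- data.frame(
    accession_a = c("P68431", "P62805", "P68431", "P68431", "P62805"),
    taxon_a = c(9606L, 9606L, 9606L, 9606L, 9606L),
    accession_b = c("Q5BIND", "Q5BIND", "Q6COIP", "Q7MOUS", "P68431"),
    taxon_b = c(9606L, 9606L, 9606L, 10090L, 9606L),
    methods = c("two-hybrid", "two-hybrid;anti tag coimmunoprecipitation",
                "anti tag coimmunoprecipitation", "two-hybrid",
                "two-hybrid"),
    stringsAsFactors = FALSE)
  files$ppi <- file.path(dir, "ppi.tsv")
  write_tsv_plain(ppi, files$ppi)

  # second-layer neighbour pairs: two anchored on partners, one not
  nbr <- data.frame(
    accession_a = c("Q9FIX1", "Q7XLNK", "Q9ZZZZ"),
    accession_b = c("Q1SECL", "Q2SECL", "Q3SECL"),
    stringsAsFactors = FALSE)
  files$neighbors <- file.path(dir, "neighbors.tsv")
  write_tsv_plain(nbr, files$neighbors)

  # ---- expected values by independent brute force ----
  oracle <- brute_force_contacts(chain_h, chain_p, cutoff)
  stopifnot(nrow(oracle) == nrow(planted))
  # expected crosslink network: apply the histone x non-histone rule with
  # plain vector operations over the table as written
  hist_acc <- catalog$accession
  a_h <- xl$accession_a %in% hist_acc
  b_h <- xl$accession_b %in% hist_acc
  q <- xor(a_h, b_h) & xl$accession_a != xl$accession_b
  pair <- unique(paste(pmin(xl$accession_a[q], xl$accession_b[q]),
                       pmax(xl$accession_a[q], xl$accession_b[q])))
  xl_partners <- setdiff(unique(c(xl$accession_a[q], xl$accession_b[q])),
                         hist_acc)
  # unique (pair, positions) combos = residue edges after dedup
  combo <- unique(paste(pmin(xl$accession_a[q], xl$accession_b[q]),
                        pmax(xl$accession_a[q], xl$accession_b[q]),
                        ifelse(xl$accession_a[q] < xl$accession_b[q],
                               xl$pos_a[q], xl$pos_b[q]),
                        ifelse(xl$accession_a[q] < xl$accession_b[q],
                               xl$pos_b[q], xl$pos_a[q])))
  # expected binary network
  binset <- default_binary_methods()
  meth <- strsplit(ppi$methods, ";")
  is_bin <- vapply(meth, function(m) any(m %in% binset), logical(1))
  pa_h <- ppi$accession_a %in% hist_acc
  pb_h <- ppi$accession_b %in% hist_acc
  pq <- is_bin & ppi$taxon_a == 9606L & ppi$taxon_b == 9606L &
    xor(pa_h, pb_h)
  ppi_pairs <- unique(paste(pmin(ppi$accession_a[pq], ppi$accession_b[pq]),
                            pmax(ppi$accession_a[pq], ppi$accession_b[pq])))

  expected <- list(
    n_chains = 2L,
    n_contacts = nrow(planted),
    contact_pairs = oracle[, c("histone_seq_pos", "partner_seq_pos")],
    contact_min_distances = planted$d[order(planted$h, planted$p)],
    protein_nodes = 2L, protein_edges = 1L,
    evidence_per_edge = 1L,
    histone_interface_uniprot = sort(planted$h + 10L),
    partner_interface_uniprot = sort(planted$p + 100L),
    residue_nodes = 2L * nrow(planted), residue_edges = nrow(planted),
    crosslink_records = sum(xl$accession_a != xl$accession_b) -
      1L,  # one duplicate (pair,positions) row collapses
    crosslink_edges = length(pair),
    crosslink_partners = length(xl_partners),
    crosslink_residue_edges = length(combo),
    binary_records = nrow(ppi), binary_flagged = sum(is_bin),
    binary_edges = length(ppi_pairs),
    global_added_nodes = 2L, global_added_edges = 2L)
  list(seed = seed, profile = "minimal", dir = dir, cutoff = cutoff,
       files = files, expected = expected)
}

fixture_curation <- function(seed, dir) {
  set.seed(seed)
  files <- list()
  catalog <- default_fixture_catalog()
  files$catalog <- file.path(dir, "catalog.tsv")
  write_tsv_plain(catalog, files$catalog)

  near <- function(y) data.frame(seq_pos = 1:3, x = 6 * (1:3), y = y, z = 0)
  mk <- function(sid, chains) {
    f <- file.path(dir, paste0(sid, ".cif"))
    write_toy_cif(sid, chains, f, assembly = list(
      oper = list(list(R = diag(3), t = c(0, 0, 0))),
      asym_ids = vapply(chains, `[[`, character(1), "asym")))
    f
  }
  # CU01, CU02: retainable (human histone + partner within contact range)
  files$CU01 <- mk("CU01", list(
    ca_chain("A", "1", "P68431", 9606L, near(0)),
    ca_chain("B", "2", "Q11AAA", 9606L, near(4))))
  files$CU02 <- mk("CU02", list(
    ca_chain("A", "1", "P62805", 9606L, near(0)),
    ca_chain("B", "2", "Q22BBB", 10090L, near(4))))  # mouse partner, kept
  # CU03: histone accession but non-focal taxon -> no_human_histone
  files$CU03 <- mk("CU03", list(
    ca_chain("A", "1", "P68431", 10090L, near(0)),
    ca_chain("B", "2", "Q33CCC", 10090L, near(4))))
  # CU04: accession-less candidate chain -> unmappable_synthetic
  files$CU04 <- mk("CU04", list(
    ca_chain("A", "1", NA_character_, NA_integer_, near(0)),
    ca_chain("B", "2", "Q44DDD", 9606L, near(4))))
  # CU05: human histone alone -> no_partner
  files$CU05 <- mk("CU05", list(
    ca_chain("A", "1", "P68431", 9606L, near(0))))

  expected <- list(
    retained = c("CU01", "CU02"),
    excluded = data.frame(
      structure_id = c("CU03", "CU04", "CU05"),
      reason = c("no_human_histone", "unmappable_synthetic", "no_partner"),
      stringsAsFactors = FALSE),
    flagged_interspecies = "CU02")
  list(seed = seed, profile = "curation", dir = dir, files = files,
       expected = expected)
}

fixture_boundary <- function(seed, dir, cutoff) {
  set.seed(seed)
  files <- list()
  # residue pair 1-1 at exactly the cutoff; pair 2-2 just outside
  hist_pos <- data.frame(seq_pos = 1:2, x = c(0, 20), y = 0, z = 0)
  part_pos <- data.frame(seq_pos = 1:2, x = c(cutoff, 20 + cutoff + 0.1),
                         y = 0, z = 0)
  chain_h <- ca_chain("A", "1", "P68431", 9606L, hist_pos)
  chain_p <- ca_chain("B", "2", "Q9BNDY", 9606L, part_pos)
  cif <- file.path(dir, "BD01.cif")
  write_toy_cif("BD01", list(chain_h, chain_p), cif,
                assembly = list(
                  oper = list(list(R = diag(3), t = c(0, 0, 0))),
                  asym_ids = c("A", "B")))
  files$cif <- cif
  catalog <- default_fixture_catalog()
  files$catalog <- file.path(dir, "catalog.tsv")
  write_tsv_plain(catalog, files$catalog)
  # inclusive rule: the pair at d == cutoff is a contact
  expected <- list(contact_at_cutoff = TRUE,
                   n_contacts_inclusive = 1L,
                   boundary_distance = cutoff)
  list(seed = seed, profile = "boundary", dir = dir, cutoff = cutoff,
       files = files, expected = expected)
}

fixture_merge <- function(seed, dir) {
  net_a <- random_toy_network(seed, n_hist = 2, n_partners = 5,
                              source_kind = "structural")
  net_b <- random_toy_network(seed + 1L, n_hist = 2, n_partners = 5,
                              source_kind = "crosslink")
  files <- list(net_a = file.path(dir, "net_a.graphml"),
                net_b = file.path(dir, "net_b.graphml"))
  write_network(net_a, files$net_a)
  write_network(net_b, files$net_b)
  # hand-enumerated union over the accession/edge lists
  union_nodes <- union(net_a$nodes$id, net_b$nodes$id)
  ek <- function(n) paste(n$edges$node_a, n$edges$node_b)
  union_edges <- union(ek(net_a), ek(net_b))
  expected <- list(n_nodes_a = nrow(net_a$nodes),
                   n_nodes_b = nrow(net_b$nodes),
                   n_union_nodes = length(union_nodes),
                   n_union_edges = length(union_edges))
  list(seed = seed, profile = "merge", dir = dir, files = files,
       expected = expected)
}
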