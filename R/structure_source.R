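# Structural evidence source: mmCIF biological assemblies -> curated
# heavy-atom interfaces -> protein- and residue-level networks.

#' Parse a PDBx/mmCIF structure into chain records
#'
#' Reads the first data block of an mmCIF file and returns one chain
#' record per polymer protein chain of the selected assembly. Hydrogens
#' and deuteriums, waters and non-polymer entities are dropped; alternate
#' locations are resolved to the highest-occupancy conformer (ties go to
#' the conformer first in file order). Chain and residue identity use
#' `label_asym_id` / `label_seq_id` (the gap-free numbering that
#' SIFTS-style mapping tables key on), never `auth_` numbering.
#'
#' With `assembly_policy = "first_assembly"` the first biological assembly
#' listed in the file is expanded by applying its symmetry operators;
#' chains produced by a non-identity operator get a `-<oper>` suffix on
#' their chain id. Files with no assembly definition fall back to the
#' asymmetric unit with a warning.
#'
#' @param source path to an mmCIF file, or its contents as a character
#'   vector of lines.
#' @param assembly_policy `"first_assembly"` (default) or
#'   `"asymmetric_unit"`.
#' @return list of chain records; each is a list with `structure_id`,
#'   `chain_id`, `entity_id`, `accession` (NA when the file maps none),
#'   `species_taxon` (NA when unstated) and `atoms`, a data frame of
#'   heavy atoms (`seq_pos`, `residue_name`, `atom_name`, `element`,
#'   `x`, `y`, `z`).
#' @export
parse_structure_cif <- function(source,
                                assembly_policy = c("first_assembly",
                                                    "asymmetric_unit")) {
  assembly_policy <- match.arg(assembly_policy)
  lines <- if (length(source) == 1 && file.exists(source))
    readLines(source, warn = FALSE) else as.character(source)
  cats <- parse_mmcif_categories(lines)

  if (is.null(cats$atom_site))
    stop("mmCIF parse error: no 'atom_site' category block found")
  at <- cats$atom_site
  needed <- c("label_asym_id", "label_seq_id", "label_comp_id",
              "type_symbol", "Cartn_x", "Cartn_y", "Cartn_z")
  missing <- setdiff(needed, names(at))
  if (length(missing))
    stop("mmCIF parse error in 'atom_site': missing item(s) ",
         paste(missing, collapse = ", "))

  structure_id <- if (!is.null(cats$entry$id)) cats$entry$id
                  else if (length(source) == 1 && file.exists(source))
                    toupper(tools::file_path_sans_ext(basename(source)))
                  else "UNKNOWN"

  # polymer entities: from the entity category when present, otherwise any
  # entity with ATOM-group records
  ent_id <- if ("label_entity_id" %in% names(at)) at$label_entity_id
            else rep(NA_character_, nrow(at))
  if (!is.null(cats$entity) && "type" %in% names(cats$entity)) {
    poly_entities <- cats$entity$id[cats$entity$type == "polymer"]
    keep_ent <- !is.na(ent_id) & ent_id %in% poly_entities
  } else if ("group_PDB" %in% names(at)) {
    atom_ents <- unique(ent_id[at$group_PDB == "ATOM"])
    keep_ent <- if (all(is.na(ent_id))) at$group_PDB == "ATOM"
                else ent_id %in% atom_ents
  } else {
    keep_ent <- rep(TRUE, nrow(at))
  }

  keep <- keep_ent &
    !toupper(at$type_symbol) %in% c("H", "D") &
    !at$label_comp_id %in% c("HOH", "DOD") &
    !is.na(at$label_seq_id)
  at <- at[keep, , drop = FALSE]
  ent_id <- ent_id[keep]
  if (!nrow(at)) return(list())

  # altloc resolution: highest occupancy, ties -> first in file order
  occ <- if ("occupancy" %in% names(at))
    suppressWarnings(as.numeric(at$occupancy)) else rep(1, nrow(at))
  occ[is.na(occ)] <- 1
  alt <- if ("label_alt_id" %in% names(at)) at$label_alt_id
         else rep(NA_character_, nrow(at))
  atom_name <- if ("label_atom_id" %in% names(at)) at$label_atom_id
               else paste0("X", seq_len(nrow(at)))
  site_key <- paste0(at$label_asym_id, "\r", at$label_seq_id, "\r", atom_name)
  if (anyDuplicated(site_key)) {
    # one conformer per atom site: highest occupancy, ties -> file order
    ord <- order(-occ, seq_len(nrow(at)))
    sel <- sort(ord[!duplicated(site_key[ord])])
    at <- at[sel, , drop = FALSE]
    ent_id <- ent_id[sel]
    atom_name <- atom_name[sel]
  }

  # per-entity annotation: UniProt accession (struct_ref) and source taxon
  acc_by_entity <- character()
  if (!is.null(cats$struct_ref)) {
    sr <- cats$struct_ref
    if (all(c("entity_id", "db_name") %in% names(sr))) {
      unp <- sr[sr$db_name == "UNP", , drop = FALSE]
      acc_col <- intersect(c("pdbx_db_accession", "db_code"), names(unp))[1]
      if (!is.na(acc_col) && nrow(unp))
        acc_by_entity <- stats::setNames(unp[[acc_col]], unp$entity_id)
    }
  }
  tax_by_entity <- character()
  for (src_cat in c("entity_src_gen", "pdbx_entity_src_syn",
                    "entity_src_nat")) {
    sc <- cats[[src_cat]]
    if (is.null(sc)) next
    tax_col <- intersect(c("pdbx_gene_src_ncbi_taxonomy_id",
                           "ncbi_taxonomy_id",
                           "pdbx_ncbi_taxonomy_id"), names(sc))[1]
    if (is.na(tax_col) || !"entity_id" %in% names(sc)) next
    new <- stats::setNames(sc[[tax_col]], sc$entity_id)
    tax_by_entity <- c(tax_by_entity,
                       new[!names(new) %in% names(tax_by_entity)])
  }

  # assembly operators
  transforms <- list(list(oper = "1", R = diag(3), t = c(0, 0, 0),
                          asym_ids = NULL, identity = TRUE))
  if (assembly_policy == "first_assembly") {
    gen <- cats$pdbx_struct_assembly_gen
    opl <- cats$pdbx_struct_oper_list
    if (is.null(gen) || is.null(opl)) {
      warning(structure_id,
              ": no biological assembly defined; using asymmetric unit")
    } else {
      first_id <- gen$assembly_id[1]
      gen <- gen[gen$assembly_id == first_id, , drop = FALSE]
      ops <- oper_matrices(opl)
      transforms <- list()
      for (r in seq_len(nrow(gen))) {
        asyms <- strsplit(gsub("[[:space:]]", "", gen$asym_id_list[r]),
                          ",")[[1]]
        for (seq_ids in parse_oper_expression(gen$oper_expression[r])) {
          missing_op <- setdiff(seq_ids, names(ops))
          if (length(missing_op))
            stop("mmCIF parse error in 'pdbx_struct_oper_list': operator ",
                 paste(missing_op, collapse = ","), " not defined")
          comp <- compose_opers(ops[seq_ids])
          transforms[[length(transforms) + 1L]] <- list(
            oper = paste(seq_ids, collapse = "x"),
            R = comp$R, t = comp$t, asym_ids = asyms,
            identity = is_identity_oper(comp))
        }
      }
    }
  }

  coords <- cbind(as.numeric(at$Cartn_x), as.numeric(at$Cartn_y),
                  as.numeric(at$Cartn_z))
  if (any(!is.finite(coords)))
    stop("mmCIF parse error in 'atom_site': non-finite coordinates")

  chains <- list()
  for (tr in transforms) {
    sel_asym <- if (is.null(tr$asym_ids)) unique(at$label_asym_id)
                else intersect(unique(at$label_asym_id), tr$asym_ids)
    for (asym in sel_asym) {
      idx <- which(at$label_asym_id == asym)
      if (!length(idx)) next
      xyz <- coords[idx, , drop = FALSE]
      if (!tr$identity)
        xyz <- sweep(xyz %*% t(tr$R), 2, tr$t, `+`)
      eid <- ent_id[idx[1]]
      atoms <- data.frame(
        seq_pos = as.integer(at$label_seq_id[idx]),
        residue_name = at$label_comp_id[idx],
        atom_name = atom_name[idx],
        element = toupper(at$type_symbol[idx]),
        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
        stringsAsFactors = FALSE)
      atoms <- atoms[order(atoms$seq_pos), , drop = FALSE]
      rownames(atoms) <- NULL
      acc <- unname(acc_by_entity[eid])
      taxon <- suppressWarnings(as.integer(unname(tax_by_entity[eid])))
      chains[[length(chains) + 1L]] <- list(
        structure_id = structure_id,
        chain_id = if (tr$identity) asym else paste0(asym, "-", tr$oper),
        entity_id = if (is.na(eid)) NA_character_ else eid,
        accession = if (length(acc) && !is.na(acc)) acc else NA_character_,
        species_taxon = if (length(taxon) && !is.na(taxon)) taxon
                        else NA_integer_,
        atoms = atoms)
    }
  }
  chains
}

#' Three-stage curation of parsed structures
#'
#' Applies, in order, the curation rules used to assemble a focal-protein
#' structure set: (i) structures with no catalog histone chain of the
#' focal species are excluded (`no_human_histone`); (ii) among the
#' remainder, structures whose candidate chains carry no accession at all
#' (synthetic constructs that cannot be mapped to a reference histone) are
#' excluded (`unmappable_synthetic`); (iii) structures with a focal
#' histone but no accession-mapped non-histone protein chain are excluded
#' (`no_partner`). Each excluded structure records the first rule that
#' fired. Partner chains of other species are retained and flagged, not
#' removed.
#'
#' @param structures named list: `structure_id` -> list of chain records
#'   from [parse_structure_cif()].
#' @param catalog a [histone_catalog()].
#' @param focal_taxon integer taxon id defining the focal species
#'   (default 9606, human).
#' @return a `curation_report`: list with `retained` (character vector of
#'   structure ids), `excluded` (data frame `structure_id`, `reason`) and
#'   `flagged_interspecies` (data frame of retained partner chains from
#'   other species).
#' @export
apply_curation_filters <- function(structures, catalog,
                                   focal_taxon = 9606L) {
  stopifnot(inherits(catalog, "histone_catalog"))
  if (nrow(catalog) == 0) stop("curation requires a non-empty catalog")
  retained <- character()
  excluded <- data.frame(structure_id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  flagged <- data.frame(structure_id = character(), chain_id = character(),
                        accession = character(), species_taxon = integer(),
                        stringsAsFactors = FALSE)
  for (sid in names(structures)) {
    chains <- structures[[sid]]
    acc <- vapply(chains, function(ch) ch$accession %||% NA_character_,
                  character(1))
    taxon <- vapply(chains, function(ch) ch$species_taxon %||% NA_integer_,
                    integer(1))
    is_hist <- !is.na(acc) & is_catalog_histone(acc, catalog)
    focal_hist <- is_hist & !is.na(taxon) & taxon == focal_taxon
    unmappable <- is.na(acc)

    if (!any(focal_hist)) {
      reason <- if (any(unmappable)) "unmappable_synthetic"
                else "no_human_histone"
      # rule order: a structure with accession-mapped chains but no focal
      # histone fails stage (i); only accession-less candidates reach (ii)
      if (!any(unmappable)) reason <- "no_human_histone"
      excluded <- rbind(excluded,
                        data.frame(structure_id = sid, reason = reason,
                                   stringsAsFactors = FALSE))
      next
    }
    partner <- !is.na(acc) & !is_hist
    if (!any(partner)) {
      excluded <- rbind(excluded,
                        data.frame(structure_id = sid, reason = "no_partner",
                                   stringsAsFactors = FALSE))
      next
    }
    retained <- c(retained, sid)
    inter <- partner & !is.na(taxon) & taxon != focal_taxon
    if (any(inter)) {
      flagged <- rbind(flagged, data.frame(
        structure_id = sid,
        chain_id = vapply(chains[inter], `[[`, character(1), "chain_id"),
        accession = acc[inter], species_taxon = taxon[inter],
        stringsAsFactors = FALSE))
    }
  }
  structure(list(retained = retained, excluded = excluded,
                 flagged_interspecies = flagged,
                 n_input = length(structures)),
            class = "curation_report")
}

#' @export
print.curation_report <- function(x, ...) {
  cat(sprintf("<curation_report> %d structures: %d retained, %d excluded\n",
              x$n_input, length(x$retained), nrow(x$excluded)))
  if (nrow(x$excluded))
    print(table(x$excluded$reason))
  invisible(x)
}

# squared cross-distances between two coordinate matrices (n x 3, m x 3)
cross_dist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

#' Extract residue contacts between two chains
#'
#' Finds every (histone residue, partner residue) pair whose minimum
#' heavy-atom distance is within the cutoff. The comparison is inclusive
#' (d <= cutoff) in double precision: a pair at exactly the cutoff is a
#' contact. Chains parsed by [parse_structure_cif()] contain heavy atoms
#' only, so hydrogens never contribute.
#'
#' @param histone_chain,partner_chain chain records from
#'   [parse_structure_cif()].
#' @param cutoff contact distance cutoff in Angstrom (default 5.0).
#' @return data frame of contacts sorted by (histone position, partner
#'   position): `structure_id`, `histone_chain`, `histone_seq_pos`,
#'   `histone_residue`, `partner_chain`, `partner_seq_pos`,
#'   `partner_residue`, `min_distance`.
#' @export
extract_contacts <- function(histone_chain, partner_chain, cutoff = 5.0) {
  stopifnot(cutoff > 0)
  empty <- data.frame(structure_id = character(),
                      histone_chain = character(),
                      histone_seq_pos = integer(),
                      histone_residue = character(),
                      partner_chain = character(),
                      partner_seq_pos = integer(),
                      partner_residue = character(),
                      min_distance = numeric(), stringsAsFactors = FALSE)
  ha <- histone_chain$atoms; pa <- partner_chain$atoms
  heavy <- function(df) df[!df$element %in% c("H", "D"), , drop = FALSE]
  ha <- heavy(ha); pa <- heavy(pa)
  if (!nrow(ha) || !nrow(pa)) {
    warning("extract_contacts: chain with zero heavy atoms")
    return(empty)
  }
  A <- as.matrix(ha[, c("x", "y", "z")])
  B <- as.matrix(pa[, c("x", "y", "z")])
  cut2 <- cutoff^2
  out <- list()
  # block over histone atoms to bound the distance-matrix size
  block <- max(1L, floor(4e6 / nrow(B)))
  for (start in seq(1L, nrow(A), by = block)) {
    idx <- start:min(start + block - 1L, nrow(A))
    d2 <- cross_dist2(A[idx, , drop = FALSE], B)
    hit <- which(d2 <= cut2, arr.ind = TRUE)
    if (!nrow(hit)) next
    out[[length(out) + 1L]] <- data.frame(
      hp = ha$seq_pos[idx[hit[, 1]]], pp = pa$seq_pos[hit[, 2]],
      d = sqrt(d2[hit]), stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  hits <- do.call(rbind, out)
  key <- paste0(hits$hp, "\r", hits$pp)
  mind <- tapply(hits$d, key, min)
  first <- !duplicated(key)
  res <- data.frame(
    structure_id = histone_chain$structure_id,
    histone_chain = histone_chain$chain_id,
    histone_seq_pos = hits$hp[first],
    histone_residue = ha$residue_name[match(hits$hp[first], ha$seq_pos)],
    partner_chain = partner_chain$chain_id,
    partner_seq_pos = hits$pp[first],
    partner_residue = pa$residue_name[match(hits$pp[first], pa$seq_pos)],
    min_distance = as.numeric(mind[key[first]]),
    stringsAsFactors = FALSE)
  res <- res[order(res$histone_seq_pos, res$partner_seq_pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Read a SIFTS-style residue mapping table
#'
#' Translates structure residue identifiers (structure id, `label_asym_id`
#' chain, `label_seq_id` position) to protein-sequence coordinates
#' (accession, 1-based position).
#'
#' @param path TSV with header
#'   `structure_id chain_id seq_pos accession uniprot_pos`.
#' @return data frame with those columns; duplicate keys are an error
#'   (the mapping must be a function).
#' @export
read_residue_mapping <- function(path) {
  df <- read_tsv_checked(path, c("structure_id", "chain_id", "seq_pos",
                                 "accession", "uniprot_pos"))
  df$seq_pos <- as.integer(df$seq_pos)
  df$uniprot_pos <- as.integer(df$uniprot_pos)
  key <- paste0(df$structure_id, "\r", df$chain_id, "\r", df$seq_pos)
  if (anyDuplicated(key))
    stop("residue mapping has duplicate keys (must be a function): ",
         basename(path))
  if (any(df$uniprot_pos < 1, na.rm = TRUE))
    stop("residue mapping: uniprot_pos must be >= 1")
  df
}

# assembly-expanded chain ids ("A-2") map through their source chain
base_chain_id <- function(chain_id) sub("-[0-9x]+$", "", chain_id)

#' Map structure contacts to protein-sequence coordinates
#'
#' Converts both sides of each contact through the residue mapping table.
#' Contacts with any unmapped residue are partitioned into `unmapped`
#' rather than silently dropped. Symmetry-generated chains (ids with an
#' operator suffix) map through their source chain.
#'
#' @param contacts data frame from [extract_contacts()].
#' @param mapping data frame from [read_residue_mapping()].
#' @return list with `mapped` (contacts plus `histone_accession`,
#'   `histone_uniprot_pos`, `partner_accession`, `partner_uniprot_pos`)
#'   and `unmapped` (the input rows that failed lookup).
#' @export
map_contacts_to_uniprot <- function(contacts, mapping) {
  if (!nrow(contacts))
    return(list(mapped = cbind(contacts,
                               data.frame(histone_accession = character(),
                                          histone_uniprot_pos = integer(),
                                          partner_accession = character(),
                                          partner_uniprot_pos = integer())),
                unmapped = contacts))
  mkey <- paste0(mapping$structure_id, "\r", mapping$chain_id, "\r",
                 mapping$seq_pos)
  hkey <- paste0(contacts$structure_id, "\r",
                 base_chain_id(contacts$histone_chain), "\r",
                 contacts$histone_seq_pos)
  pkey <- paste0(contacts$structure_id, "\r",
                 base_chain_id(contacts$partner_chain), "\r",
                 contacts$partner_seq_pos)
  hi <- match(hkey, mkey)
  pi_ <- match(pkey, mkey)
  ok <- !is.na(hi) & !is.na(pi_)
  mapped <- contacts[ok, , drop = FALSE]
  mapped$histone_accession <- normalize_accession(mapping$accession[hi[ok]])
  mapped$histone_uniprot_pos <- mapping$uniprot_pos[hi[ok]]
  mapped$partner_accession <- normalize_accession(mapping$accession[pi_[ok]])
  mapped$partner_uniprot_pos <- mapping$uniprot_pos[pi_[ok]]
  rownames(mapped) <- NULL
  unmapped <- contacts[!ok, , drop = FALSE]
  rownames(unmapped) <- NULL
  list(mapped = mapped, unmapped = unmapped)
}

#' Build structural interaction networks
#'
#' Runs the structural pipeline over curated structures: for every
#' (focal histone chain, partner chain) pair, heavy-atom contacts within
#' the cutoff are extracted, mapped to protein-sequence coordinates, and
#' collapsed into a protein-level network (one edge per unordered
#' histone/partner accession pair; one structural evidence item per
#' contributing structure, carrying the contact count and minimum
#' distance) and a residue-level network (nodes are accession:position
#' interface residues, edges are cross-protein interface residue pairs).
#'
#' Partner chains whose accession appears in `conserved_map` are
#' translated to the focal-proteome accession before node identity is
#' assigned; other-species partners without a translation are kept under
#' their own accession and flagged in provenance.
#'
#' @param structures named list: structure id -> list of chain records
#'   (the retained set from [apply_curation_filters()]).
#' @param catalog a [histone_catalog()].
#' @param mapping residue mapping data frame ([read_residue_mapping()]);
#'   `NULL` means structure residues are already in protein coordinates
#'   (identity mapping via chain accessions).
#' @param cutoff heavy-atom distance cutoff in Angstrom, default 5.0.
#' @param focal_taxon focal species taxon id, default 9606.
#' @param conserved_map optional named character vector translating
#'   conserved other-species partner accessions to focal accessions.
#' @return list with `protein` and `residue` [interaction_network()]s.
#' @export
build_structural_networks <- function(structures, catalog, mapping = NULL,
                                      cutoff = 5.0, focal_taxon = 9606L,
                                      conserved_map = NULL) {
  stopifnot(inherits(catalog, "histone_catalog"))
  if (!length(structures)) {
    warning("build_structural_networks: no retained structures")
    prov <- list(source = "structural", cutoff = cutoff, n_structures = 0)
    return(list(protein = interaction_network(granularity = "protein",
                                              provenance = prov),
                residue = interaction_network(granularity = "residue",
                                              provenance = prov)))
  }
  pe <- list()   # per (pair, structure) accumulation
  re <- list()   # residue edges
  nodes_info <- list()
  note_node <- function(acc, taxon, hist, fam) {
    if (is.null(nodes_info[[acc]]))
      nodes_info[[acc]] <<- list(taxon = taxon, hist = hist, fam = fam)
  }
  translate <- function(acc) {
    if (!is.null(conserved_map) && acc %in% names(conserved_map))
      unname(conserved_map[[acc]]) else acc
  }

  for (sid in names(structures)) {
    chains <- structures[[sid]]
    acc <- vapply(chains, function(ch) ch$accession %||% NA_character_,
                  character(1))
    taxon <- vapply(chains, function(ch) ch$species_taxon %||% NA_integer_,
                    integer(1))
    norm <- normalize_accession(acc)
    is_hist <- !is.na(acc) & norm %in% catalog$accession
    focal_hist <- is_hist & !is.na(taxon) & taxon == focal_taxon
    partner <- !is.na(acc) & !is_hist
    for (h in which(focal_hist)) {
      for (p in which(partner)) {
        contacts <- suppressWarnings(
          extract_contacts(chains[[h]], chains[[p]], cutoff))
        if (!nrow(contacts)) next
        if (!is.null(mapping)) {
          mp <- map_contacts_to_uniprot(contacts, mapping)
          mc <- mp$mapped
          if (!nrow(mc)) next
        } else {
          mc <- contacts
          mc$histone_accession <- norm[h]
          mc$histone_uniprot_pos <- mc$histone_seq_pos
          mc$partner_accession <- norm[p]
          mc$partner_uniprot_pos <- mc$partner_seq_pos
        }
        h_acc <- mc$histone_accession[1]
        p_acc <- translate(mc$partner_accession[1])
        if (h_acc == p_acc) next
        fam <- catalog$family[match(h_acc, catalog$accession)]
        note_node(h_acc, focal_taxon, TRUE, fam)
        note_node(p_acc, taxon[p], FALSE, NA_character_)
        pkey <- paste0(pmin(h_acc, p_acc), "\r", pmax(h_acc, p_acc),
                       "\r", sid)
        prev <- pe[[pkey]]
        if (is.null(prev)) {
          pe[[pkey]] <- list(a = h_acc, b = p_acc, sid = sid,
                             n_contacts = nrow(mc),
                             min_distance = min(mc$min_distance))
        } else {
          prev$n_contacts <- prev$n_contacts + nrow(mc)
          prev$min_distance <- min(prev$min_distance, mc$min_distance)
          pe[[pkey]] <- prev
        }
        for (i in seq_len(nrow(mc))) {
          re[[length(re) + 1L]] <- list(
            a_acc = h_acc, a_pos = mc$histone_uniprot_pos[i],
            b_acc = p_acc, b_pos = mc$partner_uniprot_pos[i],
            sid = sid, d = mc$min_distance[i])
        }
      }
    }
  }

  prov <- list(source = "structural", cutoff = cutoff,
               focal_taxon = focal_taxon,
               n_structures = length(structures))
  if (!length(pe)) {
    warning("build_structural_networks: no contacts found")
    return(list(protein = interaction_network(granularity = "protein",
                                              provenance = prov),
                residue = interaction_network(granularity = "residue",
                                              provenance = prov)))
  }

  accs <- names(nodes_info)
  node_df <- data.frame(
    id = accs,
    name = accs,
    species_taxon = vapply(nodes_info, function(x)
      as.integer(x$taxon %||% NA_integer_), integer(1)),
    is_histone = vapply(nodes_info, function(x) x$hist, logical(1)),
    histone_family = vapply(nodes_info, function(x)
      x$fam %||% NA_character_, character(1)),
    stringsAsFactors = FALSE)
  edge_df <- data.frame(
    node_a = vapply(pe, `[[`, character(1), "a"),
    node_b = vapply(pe, `[[`, character(1), "b"),
    stringsAsFactors = FALSE)
  edge_df$evidence <- I(lapply(pe, function(x)
    list(evidence_item("structural", x$sid,
                       list(n_contacts = x$n_contacts,
                            min_distance = x$min_distance)))))
  protein_net <- interaction_network(node_df, edge_df, "protein",
                                     provenance = prov)

  r_a <- vapply(re, function(x) paste0(x$a_acc, ":", x$a_pos), character(1))
  r_b <- vapply(re, function(x) paste0(x$b_acc, ":", x$b_pos), character(1))
  rnode <- unique(data.frame(
    id = c(r_a, r_b),
    accession = c(vapply(re, `[[`, character(1), "a_acc"),
                  vapply(re, `[[`, character(1), "b_acc")),
    position = c(vapply(re, function(x) as.integer(x$a_pos), integer(1)),
                 vapply(re, function(x) as.integer(x$b_pos), integer(1))),
    stringsAsFactors = FALSE))
  rnode$is_histone <- is_catalog_histone(rnode$accession, catalog)
  redge <- data.frame(node_a = r_a, node_b = r_b, stringsAsFactors = FALSE)
  redge$evidence <- I(lapply(re, function(x)
    list(evidence_item("structural", x$sid,
                       list(min_distance = x$d)))))
  residue_net <- interaction_network(rnode, redge, "residue",
                                     provenance = prov,
                                     dedup_evidence = TRUE)
  list(protein = protein_net, residue = residue_net)
}

#' Export interface residues as a BED-like table
#'
#' Collapses a residue-level network into per-accession interface
#' intervals (1-based inclusive), merging adjacent positions.
#'
#' @param residue_net residue-level [interaction_network()].
#' @param path output TSV path (`accession start end evidence` columns).
#' @return the interval data frame, invisibly written to `path`.
#' @export
write_interface_bed <- function(residue_net, path) {
  stopifnot(residue_net$granularity == "residue")
  nd <- residue_net$nodes
  rows <- list()
  for (acc in sort(unique(nd$accession), method = "radix")) {
    pos <- sort(unique(nd$position[nd$accession == acc]))
    if (!length(pos)) next
    brk <- c(0L, which(diff(pos) > 1L), length(pos))
    for (i in seq_len(length(brk) - 1L)) {
      seg <- pos[(brk[i] + 1L):brk[i + 1L]]
      rows[[length(rows) + 1L]] <- data.frame(
        accession = acc, start = seg[1], end = seg[length(seg)],
        evidence = "structural", stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(accession = character(), start = integer(),
                         end = integer(), evidence = character())
  write_tsv_plain(out, path)
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
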