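# Cross-linking MS evidence source: inter-protein lysine-lysine
# cross-link records -> protein-, domain- and residue-level networks.

#' Parse a cross-link record table
#'
#' Reads inter-protein cross-link records: two accessions with the
#' 1-based positions of the cross-linked lysines, a fractionation tag
#' (`fractionated` or `unfractionated` nuclei preparation) and a record
#' id. Intra-protein links (same accession on both sides) are dropped
#' with a counted warning — only inter-protein links carry interaction
#' information. Positions are trusted as peptide-mapped protein-sequence
#' coordinates; no re-mapping is applied.
#'
#' Records identical in (unordered pair, positions) are collapsed to one
#' record; the surviving record keeps the first record id and the union
#' of fraction tags, so an interaction seen in both preparations is not
#' double-counted.
#'
#' @param path TSV with header
#'   `accession_a pos_a accession_b pos_b fraction record_id`.
#' @return data frame of records with normalized accessions and a
#'   `fractions` column (`;`-joined tags).
#' @export
parse_crosslink_table <- function(path) {
  df <- read_tsv_checked(path, c("accession_a", "pos_a", "accession_b",
                                 "pos_b", "fraction", "record_id"))
  if (!nrow(df))
    return(data.frame(accession_a = character(), pos_a = integer(),
                      accession_b = character(), pos_b = integer(),
                      fractions = character(), record_id = character(),
                      stringsAsFactors = FALSE))
  for (col in c("pos_a", "pos_b")) {
    v <- suppressWarnings(as.integer(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop(sprintf("%s: non-integer %s at data line %s", basename(path),
                   col, paste(bad, collapse = ", ")))
    df[[col]] <- v
  }
  if (any(df$pos_a < 1 | df$pos_b < 1, na.rm = TRUE))
    stop(basename(path), ": cross-link positions must be >= 1")
  df$accession_a <- normalize_accession(df$accession_a)
  df$accession_b <- normalize_accession(df$accession_b)
  intra <- df$accession_a == df$accession_b
  if (any(intra)) {
    warning(sprintf("dropped %d intra-protein cross-link record(s)",
                    sum(intra)))
    df <- df[!intra, , drop = FALSE]
  }
  if (anyDuplicated(df$record_id))
    stop(basename(path), ": duplicate record_id values")
  if (!nrow(df)) {
    df$fractions <- character(0)
    return(df[, c("accession_a", "pos_a", "accession_b", "pos_b",
                  "fractions", "record_id")])
  }
  # orient pairs canonically, then collapse duplicates by (pair, positions)
  swap <- df$accession_a > df$accession_b
  tmp_a <- df$accession_a[swap]; tmp_p <- df$pos_a[swap]
  df$accession_a[swap] <- df$accession_b[swap]
  df$pos_a[swap] <- df$pos_b[swap]
  df$accession_b[swap] <- tmp_a; df$pos_b[swap] <- tmp_p
  key <- paste0(df$accession_a, "\r", df$pos_a, "\r",
                df$accession_b, "\r", df$pos_b)
  fractions <- vapply(split(as.character(df$fraction), key), function(fr)
    paste(sort(unique(fr), method = "radix"), collapse = ";"), character(1))
  first <- !duplicated(key)
  out <- df[first, c("accession_a", "pos_a", "accession_b", "pos_b",
                     "record_id"), drop = FALSE]
  out$fractions <- unname(fractions[key[first]])
  out <- out[, c("accession_a", "pos_a", "accession_b", "pos_b",
                 "fractions", "record_id")]
  rownames(out) <- NULL
  out
}

#' Write cross-link records to TSV (inverse of the parser's input format)
#' @param records data frame with parser input columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_crosslink_table <- function(records, path) {
  write_tsv_plain(records, path)
}

#' Build cross-linking interaction networks
#'
#' Keeps records in which exactly one side is a catalog histone and the
#' other a non-histone (histone-histone and non-histone pairs are
#' discarded: the interactome is defined as histone x non-histone).
#' Produces a protein-level network (one edge per unordered accession
#' pair, one cross-link evidence item per record) and a residue-level
#' network whose nodes are the cross-linked lysines (accession:position)
#' with one edge per record. When a domain annotation table is supplied a
#' domain-level network is derived from the protein-level one via
#' [to_domain_level()].
#'
#' @param records data frame from [parse_crosslink_table()].
#' @param catalog a [histone_catalog()].
#' @param focal_taxon focal species taxon id (the catalog defines the
#'   focal species; recorded in provenance).
#' @param domains optional domain annotation table
#'   ([read_domain_table()]) to also build the domain-level network.
#' @return list with `protein`, `residue` and (if `domains` given)
#'   `domain` networks.
#' @export
build_crosslink_networks <- function(records, catalog, focal_taxon = 9606L,
                                     domains = NULL) {
  stopifnot(inherits(catalog, "histone_catalog"))
  if (nrow(catalog) == 0) stop("catalog must be non-empty")
  a_hist <- is_catalog_histone(records$accession_a, catalog)
  b_hist <- is_catalog_histone(records$accession_b, catalog)
  keep <- xor(a_hist, b_hist)
  rec <- records[keep, , drop = FALSE]
  a_hist <- a_hist[keep]
  prov <- list(source = "crosslink", focal_taxon = focal_taxon,
               n_records_in = nrow(records), n_records_kept = nrow(rec))
  if (!nrow(rec)) {
    warning("build_crosslink_networks: no histone x non-histone records")
    out <- list(protein = interaction_network(granularity = "protein",
                                              provenance = prov),
                residue = interaction_network(granularity = "residue",
                                              provenance = prov))
    if (!is.null(domains))
      out$domain <- to_domain_level(out$protein, domains)
    return(out)
  }
  # orient: histone side first
  h_acc <- ifelse(a_hist, rec$accession_a, rec$accession_b)
  h_pos <- ifelse(a_hist, rec$pos_a, rec$pos_b)
  p_acc <- ifelse(a_hist, rec$accession_b, rec$accession_a)
  p_pos <- ifelse(a_hist, rec$pos_b, rec$pos_a)

  accs <- unique(c(h_acc, p_acc))
  node_df <- data.frame(
    id = accs, name = accs,
    species_taxon = rep(as.integer(focal_taxon), length(accs)),
    is_histone = is_catalog_histone(accs, catalog),
    stringsAsFactors = FALSE)
  node_df$histone_family <-
    catalog$family[match(node_df$id, catalog$accession)]
  ev <- lapply(seq_len(nrow(rec)), function(i)
    list(evidence_item("crosslink", rec$record_id[i],
                       list(pos_histone = h_pos[i],
                            pos_partner = p_pos[i],
                            fractions = rec$fractions[i]))))
  edge_df <- data.frame(node_a = h_acc, node_b = p_acc,
                        stringsAsFactors = FALSE)
  edge_df$evidence <- I(ev)
  protein_net <- interaction_network(node_df, edge_df, "protein",
                                     provenance = prov)

  r_a <- paste0(h_acc, ":", h_pos)
  r_b <- paste0(p_acc, ":", p_pos)
  rnode <- unique(data.frame(id = c(r_a, r_b),
                             accession = c(h_acc, p_acc),
                             position = as.integer(c(h_pos, p_pos)),
                             stringsAsFactors = FALSE))
  rnode$is_histone <- is_catalog_histone(rnode$accession, catalog)
  redge <- data.frame(node_a = r_a, node_b = r_b, stringsAsFactors = FALSE)
  redge$evidence <- I(ev)
  residue_net <- interaction_network(rnode, redge, "residue",
                                     provenance = prov)
  out <- list(protein = protein_net, residue = residue_net)
  if (!is.null(domains))
    out$domain <- to_domain_level(protein_net, domains,
                                  interface_hint = residue_net)
  out
}
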