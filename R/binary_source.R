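# High-throughput binary-PPI evidence source (APID-style tables).

#' Default "binary" detection-method codes
#'
#' Method classes taken to attest a direct physical interaction between
#' two proteins, as opposed to co-membership in a purified complex:
#' yeast two-hybrid and derivatives, protein complementation assays, and
#' far-western blotting. PSI-MI-style lower-case labels; override via the
#' `binary_method_codes` argument/config key.
#'
#' @return character vector of method codes.
#' @export
default_binary_methods <- function() {
  c("two-hybrid", "two-hybrid-array", "two-hybrid-fragment-pooling",
    "reverse-two-hybrid", "lexa-dimerization",
    "protein-complementation", "bimolecular-fluorescence-complementation",
    "split-luciferase", "far-western-blotting")
}

#' Parse a binary-PPI table
#'
#' Reads APID-style interaction rows: two accessions with their species
#' taxa and the `;`-separated set of detection-method codes supporting
#' the pair. A record is flagged `is_binary` when at least one of its
#' methods is in the configured binary-method set.
#'
#' @param path TSV with header
#'   `accession_a taxon_a accession_b taxon_b methods`.
#' @param binary_method_codes character vector of method codes counted
#'   as binary; defaults to [default_binary_methods()].
#' @return data frame with normalized accessions, integer taxa, a
#'   `methods` list column and `is_binary` flag.
#' @export
parse_ppi_table <- function(path,
                            binary_method_codes = default_binary_methods()) {
  df <- read_tsv_checked(path, c("accession_a", "taxon_a", "accession_b",
                                 "taxon_b", "methods"))
  if (!nrow(df)) {
    out <- data.frame(accession_a = character(), taxon_a = integer(),
                      accession_b = character(), taxon_b = integer(),
                      stringsAsFactors = FALSE)
    out$methods <- list()
    out$is_binary <- logical(0)
    return(out)
  }
  empty <- which(is.na(df$methods) | !nzchar(trimws(df$methods)))
  if (length(empty))
    stop(sprintf("%s: empty methods field at data line %s", basename(path),
                 paste(empty, collapse = ", ")))
  out <- data.frame(
    accession_a = normalize_accession(df$accession_a),
    taxon_a = as.integer(df$taxon_a),
    accession_b = normalize_accession(df$accession_b),
    taxon_b = as.integer(df$taxon_b),
    stringsAsFactors = FALSE)
  out$methods <- lapply(strsplit(as.character(df$methods), ";"), trimws)
  out$is_binary <- vapply(out$methods, function(m)
    length(intersect(m, binary_method_codes)) > 0, logical(1))
  out
}

#' Build the high-throughput protein-level network
#'
#' Keeps records that (a) are supported by at least one binary detection
#' method, (b) are intra-species at the focal taxon (inter-species pairs
#' are excluded), and (c) connect exactly one catalog histone to a
#' non-histone. Qualifying records collapse to one edge per unordered
#' accession pair; evidence items carry the matching binary method codes
#' (one item per code). Only a protein-level network is built: binary
#' interaction tables carry no interface information from which domain-
#' or residue-level networks could be derived.
#'
#' @param records data frame from [parse_ppi_table()].
#' @param catalog a [histone_catalog()].
#' @param focal_taxon focal species taxon id, default 9606.
#' @param binary_method_codes the binary-method set used to derive
#'   per-edge evidence items (defaults to [default_binary_methods()]).
#' @return a protein-level [interaction_network()].
#' @export
build_binary_network <- function(records, catalog, focal_taxon = 9606L,
                                 binary_method_codes =
                                   default_binary_methods()) {
  stopifnot(inherits(catalog, "histone_catalog"))
  if (nrow(catalog) == 0) stop("catalog must be non-empty")
  prov <- list(source = "binary", focal_taxon = focal_taxon,
               n_records_in = nrow(records))
  if (!nrow(records))
    return(interaction_network(granularity = "protein", provenance = prov))
  a_hist <- is_catalog_histone(records$accession_a, catalog)
  b_hist <- is_catalog_histone(records$accession_b, catalog)
  keep <- records$is_binary &
    records$taxon_a == focal_taxon & records$taxon_b == focal_taxon &
    xor(a_hist, b_hist) &
    records$accession_a != records$accession_b
  rec <- records[keep, , drop = FALSE]
  a_hist <- a_hist[keep]
  prov$n_records_kept <- nrow(rec)
  if (!nrow(rec)) {
    warning("build_binary_network: no qualifying binary records")
    return(interaction_network(granularity = "protein", provenance = prov))
  }
  h_acc <- ifelse(a_hist, rec$accession_a, rec$accession_b)
  p_acc <- ifelse(a_hist, rec$accession_b, rec$accession_a)
  accs <- unique(c(h_acc, p_acc))
  node_df <- data.frame(
    id = accs, name = accs,
    species_taxon = rep(as.integer(focal_taxon), length(accs)),
    is_histone = is_catalog_histone(accs, catalog),
    stringsAsFactors = FALSE)
  node_df$histone_family <-
    catalog$family[match(node_df$id, catalog$accession)]
  ev <- lapply(seq_len(nrow(rec)), function(i) {
    codes <- sort(intersect(rec$methods[[i]], binary_method_codes),
                  method = "radix")
    lapply(codes, function(cd) evidence_item("binary", cd))
  })
  edge_df <- data.frame(node_a = h_acc, node_b = p_acc,
                        stringsAsFactors = FALSE)
  edge_df$evidence <- I(ev)
  interaction_network(node_df, edge_df, "protein", provenance = prov,
                      dedup_evidence = TRUE)
}
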