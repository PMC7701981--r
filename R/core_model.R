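# Recognised histone families. CENP-A is the centromeric H3 variant; H1/H5
# are linker histones, the rest core histones.
HISTONE_FAMILIES <- c("H1", "H2A", "H2B", "H3", "H4", "H5", "CENP-A")

# Text-search keywords historically used to pull histone/nucleosome
# complexes from a structure archive; kept as documented metadata on the
# catalog (the toolkit itself operates on locally supplied files).
HISTONE_KEYWORDS <- c("Histone", "H1", "H2A", "H2B", "H3", "H4", "H5",
                      "CENP-A")

EVIDENCE_KINDS <- c("structural", "crosslink", "binary")
GRANULARITIES  <- c("protein", "domain", "residue")
LAYERS         <- c("core", "global")

#' Normalize a protein accession
#'
#' Strips surrounding whitespace and a trailing isoform suffix (e.g.
#' `"P68431-2"` becomes `"P68431"`) so that node identity comparisons
#' operate on the canonical accession. Isoforms of one entry collapse to a
#' single node.
#'
#' @param x character vector of accessions.
#' @return character vector of normalized accessions.
#' @export
#' @examples
#' normalize_accession(c("P68431-2", " Q71DI3 "))
normalize_accession <- function(x) {
  sub("-[0-9]+$", "", trimws(as.character(x)))
}

#' Construct a histone catalog
#'
#' The catalog is the reference defining which accessions are histones,
#' their family, variant label and species. It stands in for a curated
#' histone sequence database: any accession not listed is treated as a
#' non-histone by every builder.
#'
#' @param accession character vector of protein accessions (unique after
#'   normalization).
#' @param family histone family, one of `"H1"`, `"H2A"`, `"H2B"`, `"H3"`,
#'   `"H4"`, `"H5"`, `"CENP-A"`.
#' @param variant free-text variant label (e.g. `"H3.1"`, `"macroH2A"`).
#' @param taxon integer NCBI taxon id of the species.
#' @return a `histone_catalog` object (a data frame with columns
#'   `accession`, `family`, `variant`, `taxon`).
#' @export
histone_catalog <- function(accession, family, variant = family,
                            taxon = 9606L) {
  accession <- normalize_accession(accession)
  family <- as.character(family)
  n <- length(accession)
  variant <- rep_len(as.character(variant), n)
  taxon <- rep_len(as.integer(taxon), n)
  if (anyDuplicated(accession))
    stop("histone_catalog: duplicate accessions: ",
         paste(unique(accession[duplicated(accession)]), collapse = ", "))
  bad <- setdiff(family, HISTONE_FAMILIES)
  if (length(bad))
    stop("histone_catalog: unknown histone family: ",
         paste(bad, collapse = ", "))
  cat_df <- data.frame(accession = accession, family = family,
                       variant = variant, taxon = taxon,
                       stringsAsFactors = FALSE)
  cat_df <- cat_df[order(cat_df$accession, method = "radix"), , drop = FALSE]
  rownames(cat_df) <- NULL
  attr(cat_df, "keywords") <- HISTONE_KEYWORDS
  class(cat_df) <- c("histone_catalog", "data.frame")
  cat_df
}

#' Read a histone catalog from a TSV file
#'
#' Expected columns: `accession`, `family`, `variant`, `taxon`.
#'
#' @param path path to a tab-separated file with a header line.
#' @return a [histone_catalog()] object.
#' @export
read_histone_catalog <- function(path) {
  df <- read_tsv_checked(path, c("accession", "family", "variant", "taxon"))
  histone_catalog(df$accession, df$family, df$variant, as.integer(df$taxon))
}

#' Write a histone catalog to TSV
#' @param catalog a [histone_catalog()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_histone_catalog <- function(catalog, path) {
  write_tsv_plain(as.data.frame(catalog), path)
}

# TRUE for accessions present in the catalog (after normalization).
is_catalog_histone <- function(accession, catalog) {
  normalize_accession(accession) %in% catalog$accession
}

#' Create an evidence item
#'
#' One piece of provenance attached to a network edge: which evidence
#' source observed the interaction and under which identifier (a structure
#' id, a cross-link record id, or a detection-method code), plus free-form
#' attributes such as the minimum heavy-atom distance.
#'
#' @param source_kind one of `"structural"`, `"crosslink"`, `"binary"`.
#' @param source_id non-empty identifier within that source.
#' @param attributes named list of scalar attributes.
#' @return a list of class `evidence_item`.
#' @export
evidence_item <- function(source_kind, source_id, attributes = list()) {
  source_kind <- match.arg(source_kind, EVIDENCE_KINDS)
  source_id <- as.character(source_id)
  if (!nzchar(source_id)) stop("evidence_item: source_id must be non-empty")
  structure(list(source_kind = source_kind, source_id = source_id,
                 attributes = attributes),
            class = "evidence_item")
}

# Canonical string key used to deduplicate evidence across merges.
evidence_key <- function(ev) paste0(ev$source_kind, "\r", ev$source_id)

# Node-schema registry: column names and types per granularity, used by the
# constructor to complete partial node tables and by readers to restore
# types after (string-typed) serialization.
node_schema <- function(granularity) {
  switch(granularity,
    protein = list(id = "character", name = "character",
                   species_taxon = "integer", is_histone = "logical",
                   histone_family = "character",
                   domain_families = "character"),
    domain  = list(id = "character", name = "character",
                   is_histone = "logical", histone_family = "character",
                   members = "character"),
    residue = list(id = "character", accession = "character",
                   position = "integer", is_histone = "logical"),
    stop("unknown granularity: ", granularity)
  )
}

# Fill missing node columns with typed NA/defaults and order columns.
complete_nodes <- function(nodes, granularity) {
  schema <- node_schema(granularity)
  out <- data.frame(id = as.character(nodes$id), stringsAsFactors = FALSE)
  for (col in names(schema)) {
    if (col == "id") next
    if (col %in% names(nodes)) {
      v <- nodes[[col]]
      out[[col]] <- switch(schema[[col]],
                           character = as.character(v),
                           integer = as.integer(v),
                           logical = as.logical(v))
    } else {
      out[[col]] <- rep(switch(schema[[col]],
                               character = NA_character_,
                               integer = NA_integer_,
                               logical = NA), nrow(out))
    }
  }
  if ("is_histone" %in% names(out))
    out$is_histone[is.na(out$is_histone)] <- FALSE
  out
}

#' Construct an interaction network
#'
#' The central container: a set of nodes at one granularity (whole
#' proteins, conserved-domain families, or individual residues) and a set
#' of unordered, evidence-carrying edges. Edges are canonicalized
#' (`node_a <= node_b`), duplicate unordered edges are collapsed with
#' their evidence lists concatenated, and self-edges are rejected. Rows
#' are sorted bytewise so equal networks serialize identically.
#'
#' @param nodes data frame with at least an `id` column; missing schema
#'   columns for the granularity are completed with `NA`.
#' @param edges data frame with columns `node_a`, `node_b`, optional
#'   `layer` (default `"core"`), and optional list column `evidence`.
#' @param granularity `"protein"`, `"domain"` or `"residue"`.
#' @param provenance named list of build metadata (input files, cutoff,
#'   parameters). Never includes wall-clock content, so builds are
#'   byte-reproducible.
#' @param dedup_evidence collapse evidence items that share
#'   `(source_kind, source_id)` on one edge (used by [merge_networks()]).
#' @return an object of class `interaction_network`.
#' @export
interaction_network <- function(nodes = NULL, edges = NULL,
                                granularity = "protein",
                                provenance = list(),
                                dedup_evidence = FALSE) {
  granularity <- match.arg(granularity, GRANULARITIES)
  if (is.null(nodes)) nodes <- data.frame(id = character())
  if (is.null(edges))
    edges <- data.frame(node_a = character(), node_b = character())
  nodes <- complete_nodes(nodes, granularity)
  nodes <- nodes[!duplicated(nodes$id), , drop = FALSE]
  nodes <- nodes[order(nodes$id, method = "radix"), , drop = FALSE]
  rownames(nodes) <- NULL

  ne <- nrow(edges)
  node_a <- as.character(edges$node_a)
  node_b <- as.character(edges$node_b)
  layer <- if ("layer" %in% names(edges)) as.character(edges$layer)
           else rep("core", ne)
  layer[is.na(layer)] <- "core"
  if (ne && any(!layer %in% LAYERS))
    stop("interaction_network: layer must be 'core' or 'global'")
  evidence <- if ("evidence" %in% names(edges)) as.list(edges$evidence)
              else rep(list(list()), ne)

  if (any(node_a == node_b))
    stop("interaction_network: self-edges are not allowed (",
         paste(unique(node_a[node_a == node_b]), collapse = ", "), ")")

  # canonical unordered orientation
  swap <- node_a > node_b
  tmp <- node_a[swap]; node_a[swap] <- node_b[swap]; node_b[swap] <- tmp

  key <- paste0(node_a, "\r", node_b)
  if (anyDuplicated(key)) {
    first <- !duplicated(key)
    idx <- match(key, key[first])
    merged_ev <- vector("list", sum(first))
    merged_layer <- character(sum(first))
    for (i in seq_len(ne)) {
      j <- idx[i]
      merged_ev[[j]] <- c(merged_ev[[j]], evidence[[i]])
    }
    merged_layer <- vapply(split(layer, idx), function(l)
      if (any(l == "core")) "core" else "global", character(1))
    node_a <- node_a[first]; node_b <- node_b[first]
    layer <- merged_layer[as.character(seq_len(sum(first)))]
    evidence <- merged_ev
    ne <- length(node_a)
  }

  if (dedup_evidence && ne) {
    evidence <- lapply(evidence, function(evl) {
      if (!length(evl)) return(evl)
      evl[!duplicated(vapply(evl, evidence_key, character(1)))]
    })
  }

  dangling <- setdiff(c(node_a, node_b), nodes$id)
  if (length(dangling))
    stop("interaction_network: edge endpoints without nodes: ",
         paste(dangling, collapse = ", "))

  ord <- order(node_a, node_b, method = "radix")
  net <- structure(list(
    granularity = granularity,
    nodes = nodes,
    edges = data.frame(node_a = node_a[ord], node_b = node_b[ord],
                       layer = layer[ord], stringsAsFactors = FALSE),
    evidence = evidence[ord],
    provenance = provenance
  ), class = "interaction_network")
  net
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network> granularity=%s: %d nodes, %d edges (%d core, %d global)\n",
              x$granularity, nrow(x$nodes), nrow(x$edges),
              sum(x$edges$layer == "core"), sum(x$edges$layer == "global")))
  if (nrow(x$nodes) && "is_histone" %in% names(x$nodes))
    cat(sprintf("  histone nodes: %d\n", sum(x$nodes$is_histone)))
  invisible(x)
}

#' Validate an interaction network
#'
#' Scans a network for invariant violations: edge endpoints without a
#' node, duplicate unordered edges, self-edges, edges with empty evidence,
#' malformed residue-node identifiers, and (when a catalog is supplied)
#' histone flags inconsistent with the catalog. The network is not
#' modified.
#'
#' @param net an [interaction_network()].
#' @param catalog optional [histone_catalog()] to check histone flags
#'   against.
#' @return data frame of violations with columns `rule` and `detail`;
#'   zero rows means the network is valid.
#' @export
validate_network <- function(net, catalog = NULL) {
  stopifnot(inherits(net, "interaction_network"))
  viol <- list()
  add <- function(rule, detail)
    viol[[length(viol) + 1L]] <<- data.frame(rule = rule, detail = detail,
                                             stringsAsFactors = FALSE)
  e <- net$edges
  self <- e$node_a == e$node_b
  for (id in unique(e$node_a[self])) add("self_edge", id)

  key <- paste0(pmin(e$node_a, e$node_b), "\r", pmax(e$node_a, e$node_b))
  for (k in unique(key[duplicated(key)]))
    add("duplicate_edge", gsub("\r", " -- ", k))

  dangling <- setdiff(c(e$node_a, e$node_b), net$nodes$id)
  for (id in dangling) add("dangling_endpoint", id)

  if (length(net$evidence) != nrow(e)) {
    add("evidence_length", sprintf("%d evidence lists for %d edges",
                                   length(net$evidence), nrow(e)))
  } else if (nrow(e)) {
    empty <- which(!vapply(net$evidence, length, integer(1)))
    for (i in empty)
      add("empty_evidence", paste(e$node_a[i], "--", e$node_b[i]))
  }

  if (net$granularity == "residue" && nrow(net$nodes)) {
    bad <- !grepl("^[^:]+:[0-9]+$", net$nodes$id)
    for (id in net$nodes$id[bad]) add("bad_residue_id", id)
  }

  if (!is.null(catalog) && "is_histone" %in% names(net$nodes) &&
      nrow(net$nodes)) {
    acc <- if (net$granularity == "residue") net$nodes$accession
           else net$nodes$id
    in_cat <- is_catalog_histone(acc, catalog)
    mism <- which(net$granularity != "domain" &
                    net$nodes$is_histone != in_cat)
    for (i in mism)
      add("histone_flag_mismatch", net$nodes$id[i])
  }

  if (length(viol)) do.call(rbind, viol)
  else data.frame(rule = character(), detail = character(),
                  stringsAsFactors = FALSE)
}

# Canonical serialization of an evidence list for equality comparison:
# sorted multiset of (kind, id, attributes-as-JSON).
evidence_signature <- function(evl) {
  if (!length(evl)) return(character())
  sig <- vapply(evl, function(ev) {
    at <- ev$attributes
    if (length(at)) at <- at[order(names(at), method = "radix")]
    paste0(ev$source_kind, "\r", ev$source_id, "\r",
           jsonlite::toJSON(at, auto_unbox = TRUE, digits = NA))
  }, character(1))
  sort(sig, method = "radix")
}

#' Compare two networks for structural equality
#'
#' Networks are equal when they share granularity, node identifier sets
#' with identical attributes, edge sets (unordered pairs with layers), and
#' per-edge evidence multisets. Provenance is excluded, so a round trip
#' through a lossless serialization format compares equal.
#'
#' @param a,b [interaction_network()] objects.
#' @param check_attributes also compare node attribute columns.
#' @return `TRUE` or `FALSE`.
#' @export
network_equal <- function(a, b, check_attributes = TRUE) {
  if (a$granularity != b$granularity) return(FALSE)
  if (!identical(a$nodes$id, b$nodes$id)) return(FALSE)
  if (check_attributes) {
    na_ <- a$nodes; nb <- b$nodes
    for (col in setdiff(names(na_), "id")) {
      if (!col %in% names(nb)) return(FALSE)
      va <- na_[[col]]; vb <- nb[[col]]
      same <- (is.na(va) & is.na(vb)) | (!is.na(va) & !is.na(vb) & va == vb)
      if (!all(same)) return(FALSE)
    }
  }
  if (nrow(a$edges) != nrow(b$edges)) return(FALSE)
  if (!identical(a$edges$node_a, b$edges$node_a)) return(FALSE)
  if (!identical(a$edges$node_b, b$edges$node_b)) return(FALSE)
  if (!identical(a$edges$layer, b$edges$layer)) return(FALSE)
  for (i in seq_len(nrow(a$edges))) {
    if (!identical(evidence_signature(a$evidence[[i]]),
                   evidence_signature(b$evidence[[i]])))
      return(FALSE)
  }
  TRUE
}

# ---- shared TSV helpers -------------------------------------------------

read_tsv_checked <- function(path, required_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "", comment.char = "")
  missing <- setdiff(required_cols, names(df))
  if (length(missing))
    stop(sprintf("%s: missing required column(s): %s", basename(path),
                 paste(missing, collapse = ", ")))
  df
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "")
  invisible(path)
}
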