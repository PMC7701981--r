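# Granularity and layer transformations: domain-level grouping, global
# second-layer expansion, multi-network merge, summary statistics.

#' Read a domain annotation table
#'
#' Conserved-domain family annotations per protein: family id and name
#' plus the 1-based inclusive sequence range the family model covers.
#'
#' @param path TSV with header `accession family_id family_name start end`.
#' @return data frame with those columns (accessions normalized).
#' @export
read_domain_table <- function(path) {
  df <- read_tsv_checked(path, c("accession", "family_id", "family_name",
                                 "start", "end"))
  df$accession <- normalize_accession(df$accession)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(df$start > df$end, na.rm = TRUE))
    stop(basename(path), ": domain ranges must satisfy start <= end")
  if (any(!nzchar(df$family_id)))
    stop(basename(path), ": empty family_id")
  df
}

# families annotated for one accession, optionally restricted to those
# overlapping interface residues; returns zero rows when unannotated
families_for <- function(acc, domains, iface_pos = NULL) {
  rows <- domains[domains$accession == acc, , drop = FALSE]
  if (!nrow(rows)) return(rows)
  if (length(iface_pos)) {
    hit <- vapply(seq_len(nrow(rows)), function(i)
      any(iface_pos >= rows$start[i] & iface_pos <= rows$end[i]),
      logical(1))
    if (any(hit)) rows <- rows[hit, , drop = FALSE]
  }
  rows
}

#' Collapse a protein-level network to domain level
#'
#' Groups non-histone partner proteins by conserved-domain family: every
#' partner node is replaced by a domain-family node and proteins sharing
#' a family collapse into one node, with edge evidence unioned. Histone
#' nodes pass through unchanged, so the result remains a histone x
#' domain-family bipartite-style network. Partners with no annotation row
#' are kept as singleton pseudo-family nodes named by their accession and
#' counted in a warning.
#'
#' Partners annotated with several families map to a single
#' representative node by default (`multi_family = "collapse"`): the
#' family overlapping the partner's interface residues when
#' `interface_hint` supplies them (most overlapping residues wins, ties
#' broken by family id), otherwise the first family in annotation-table
#' order. This keeps the collapse edge-count non-increasing.
#' `multi_family = "expand"` instead maps such partners to every
#' annotated family, which can split one protein edge into several
#' domain edges.
#'
#' @param net protein-level [interaction_network()].
#' @param domains domain annotation table ([read_domain_table()]).
#' @param interface_hint optional residue-level network supplying
#'   interface residues used to pick the interacting family.
#' @param multi_family `"collapse"` (default) or `"expand"`.
#' @return a domain-level [interaction_network()].
#' @export
to_domain_level <- function(net, domains, interface_hint = NULL,
                            multi_family = c("collapse", "expand")) {
  stopifnot(inherits(net, "interaction_network"))
  if (net$granularity != "protein")
    stop("to_domain_level requires a protein-level network")
  multi_family <- match.arg(multi_family)
  if (is.null(domains))
    domains <- data.frame(accession = character(), family_id = character(),
                          family_name = character(), start = integer(),
                          end = integer(), stringsAsFactors = FALSE)
  iface <- NULL
  if (!is.null(interface_hint)) {
    stopifnot(interface_hint$granularity == "residue")
    iface <- split(interface_hint$nodes$position,
                   interface_hint$nodes$accession)
  }

  nd <- net$nodes
  unannotated <- character()
  # per protein node: data frame of target domain nodes (id, name, member)
  target <- list()
  for (i in seq_len(nrow(nd))) {
    acc <- nd$id[i]
    if (isTRUE(nd$is_histone[i])) {
      target[[acc]] <- data.frame(id = acc, name = nd$name[i] %||% acc,
                                  is_histone = TRUE,
                                  histone_family = nd$histone_family[i],
                                  stringsAsFactors = FALSE)
      next
    }
    fam <- families_for(acc, domains, iface[[acc]])
    if (!nrow(fam)) {
      unannotated <- c(unannotated, acc)
      target[[acc]] <- data.frame(id = acc, name = acc, is_histone = FALSE,
                                  histone_family = NA_character_,
                                  stringsAsFactors = FALSE)
      next
    }
    if (multi_family == "collapse" && nrow(fam) > 1) {
      ipos <- iface[[acc]]
      if (length(ipos)) {
        overlap <- vapply(seq_len(nrow(fam)), function(j)
          sum(ipos >= fam$start[j] & ipos <= fam$end[j]), integer(1))
        fam <- fam[order(-overlap, fam$family_id,
                         method = "radix"), , drop = FALSE]
      }
      fam <- fam[1, , drop = FALSE]
    }
    target[[acc]] <- data.frame(id = fam$family_id,
                                name = fam$family_name,
                                is_histone = FALSE,
                                histone_family = NA_character_,
                                stringsAsFactors = FALSE)
  }
  if (length(unannotated))
    warning(sprintf(
      "to_domain_level: %d partner(s) without domain annotation kept as singleton pseudo-families: %s",
      length(unannotated), paste(unannotated, collapse = ", ")))

  # node table with member accessions
  all_nodes <- do.call(rbind, unname(target))
  members <- vapply(split(rep(names(target),
                              vapply(target, nrow, integer(1))),
                          all_nodes$id),
                    function(m) paste(sort(unique(m), method = "radix"),
                                      collapse = ";"), character(1))
  node_df <- all_nodes[!duplicated(all_nodes$id), , drop = FALSE]
  node_df$members <- unname(members[node_df$id])

  e <- net$edges
  new_edges <- list()
  new_ev <- list()
  for (i in seq_len(nrow(e))) {
    ta <- target[[e$node_a[i]]]; tb <- target[[e$node_b[i]]]
    for (ia in seq_len(nrow(ta))) for (ib in seq_len(nrow(tb))) {
      if (ta$id[ia] == tb$id[ib]) next  # proteins collapsing to one family
      new_edges[[length(new_edges) + 1L]] <-
        data.frame(node_a = ta$id[ia], node_b = tb$id[ib],
                   layer = e$layer[i], stringsAsFactors = FALSE)
      new_ev[[length(new_ev) + 1L]] <- net$evidence[[i]]
    }
  }
  edge_df <- if (length(new_edges)) do.call(rbind, new_edges)
             else data.frame(node_a = character(), node_b = character(),
                             layer = character(), stringsAsFactors = FALSE)
  edge_df$evidence <- I(new_ev)
  prov <- net$provenance
  prov$granularity_collapsed_from <- "protein"
  prov$multi_family <- multi_family
  prov$n_unannotated <- length(unannotated)
  interaction_network(node_df, edge_df, "domain", provenance = prov,
                      dedup_evidence = TRUE)
}

#' Expand a core network by one partner-of-partner layer
#'
#' Builds a "global" interactome: for every non-histone core node P, each
#' pair (P, Q) in the neighbour table whose other endpoint Q is not
#' already in the core adds node Q and a `layer = "global"` edge P-Q.
#' Core nodes and edges are untouched; no second expansion step is
#' applied (Q's own neighbours are ignored), and pairs touching no core
#' node are ignored.
#'
#' @param core protein-level [interaction_network()].
#' @param neighbor_table data frame with columns `accession_a`,
#'   `accession_b` (one row per known partner interaction).
#' @param source_kind evidence kind recorded on added edges; defaults to
#'   the core network's provenance source, else `"binary"`.
#' @return the expanded [interaction_network()].
#' @export
expand_global <- function(core, neighbor_table, source_kind = NULL) {
  stopifnot(inherits(core, "interaction_network"))
  if (core$granularity != "protein")
    stop("expand_global requires a protein-level network")
  if (is.null(source_kind))
    source_kind <- core$provenance$source %||% "binary"
  source_kind <- match.arg(source_kind, EVIDENCE_KINDS)
  if (is.null(neighbor_table) || !nrow(neighbor_table)) return(core)
  a <- normalize_accession(neighbor_table$accession_a)
  b <- normalize_accession(neighbor_table$accession_b)
  core_ids <- core$nodes$id
  anchor_ids <- core_ids[!core$nodes$is_histone]

  a_in <- a %in% anchor_ids; b_in <- b %in% anchor_ids
  a_core <- a %in% core_ids; b_core <- b %in% core_ids
  # exactly one endpoint anchored on a non-histone core node, the other new
  sel <- (a_in & !b_core) | (b_in & !a_core)
  sel <- sel & a != b
  if (!any(sel)) return(core)
  p <- ifelse(a_in[sel], a[sel], b[sel])
  q <- ifelse(a_in[sel], b[sel], a[sel])

  new_nodes <- unique(q)
  node_df <- rbind(core$nodes,
                   complete_nodes(data.frame(id = new_nodes,
                                             name = new_nodes,
                                             is_histone = FALSE,
                                             stringsAsFactors = FALSE),
                                  "protein"))
  ev <- lapply(seq_along(p), function(i)
    list(evidence_item(source_kind, paste0("neighbor:", p[i], "|", q[i]),
                       list(layer = "global"))))
  edge_df <- data.frame(node_a = c(core$edges$node_a, p),
                        node_b = c(core$edges$node_b, q),
                        layer = c(core$edges$layer,
                                  rep("global", length(p))),
                        stringsAsFactors = FALSE)
  edge_df$evidence <- I(c(core$evidence, ev))
  prov <- core$provenance
  prov$layer <- "global"
  prov$n_second_layer_pairs <- length(p)
  interaction_network(node_df, edge_df, "protein", provenance = prov,
                      dedup_evidence = TRUE)
}

#' Merge interaction networks by accession
#'
#' Combines networks from different evidence sources into one: nodes are
#' unioned by normalized accession, edges by unordered accession pair,
#' and evidence lists are concatenated and deduplicated by
#' (source kind, source id). An edge that is `core` in any input stays
#' `core`. Node attributes merge field-wise with first-input precedence.
#' All inputs must share one granularity; mixing granularities is an
#' error rather than a coercion.
#'
#' @param nets list of [interaction_network()]s (or several networks as
#'   `...`-style list). `merge_networks(list(n))` returns `n` unchanged.
#' @return the merged [interaction_network()].
#' @export
merge_networks <- function(nets) {
  if (inherits(nets, "interaction_network")) nets <- list(nets)
  stopifnot(length(nets) >= 1)
  gran <- unique(vapply(nets, `[[`, character(1), "granularity"))
  if (length(gran) != 1)
    stop("merge_networks: granularity mismatch: ",
         paste(gran, collapse = " vs "))
  nodes <- do.call(rbind, lapply(nets, function(n)
    complete_nodes(n$nodes, gran)))
  # first-input precedence per node id, but fill NA attributes from later
  # inputs so partial annotations combine
  merged_nodes <- nodes[!duplicated(nodes$id), , drop = FALSE]
  for (col in setdiff(names(nodes), "id")) {
    miss <- which(is.na(merged_nodes[[col]]))
    if (!length(miss)) next
    for (i in miss) {
      cand <- nodes[[col]][nodes$id == merged_nodes$id[i]]
      cand <- cand[!is.na(cand)]
      if (length(cand)) merged_nodes[[col]][i] <- cand[1]
    }
  }
  edge_df <- do.call(rbind, lapply(nets, function(n)
    n$edges[, c("node_a", "node_b", "layer"), drop = FALSE]))
  edge_df$evidence <- I(do.call(c, lapply(nets, `[[`, "evidence")))
  provs <- lapply(nets, `[[`, "provenance")
  prov <- list(source = "merged",
               merged_sources = vapply(provs, function(p)
                 p$source %||% "unknown", character(1)))
  interaction_network(merged_nodes, edge_df, gran, provenance = prov,
                      dedup_evidence = TRUE)
}

#' Summary statistics of a network
#'
#' @param net an [interaction_network()].
#' @param catalog optional [histone_catalog()]; when given, histone
#'   status is re-derived from it instead of trusting node flags.
#' @param domains optional domain annotation table used to count domain
#'   families represented among non-histone protein nodes.
#' @return a `network_stats` list: `n_nodes`, `n_edges`,
#'   `n_unique_partners` (distinct non-histone protein accessions),
#'   `n_domain_families`, plus `n_core_edges` / `n_global_edges`.
#' @export
network_stats <- function(net, catalog = NULL, domains = NULL) {
  stopifnot(inherits(net, "interaction_network"))
  nd <- net$nodes
  hist_flag <- if (!is.null(catalog)) {
    acc <- if (net$granularity == "residue") nd$accession else nd$id
    if (net$granularity == "domain") nd$is_histone
    else is_catalog_histone(acc, catalog)
  } else nd$is_histone
  # at domain granularity a "partner" is a non-histone family node, so the
  # partner count never exceeds the node count at any granularity
  partner_acc <- switch(net$granularity,
    protein = nd$id[!hist_flag],
    residue = unique(nd$accession[!hist_flag]),
    domain = nd$id[!hist_flag])
  n_fam <- if (net$granularity == "domain") {
    sum(!hist_flag)
  } else if (!is.null(domains)) {
    length(unique(domains$family_id[domains$accession %in% partner_acc]))
  } else NA_integer_
  structure(list(
    n_nodes = nrow(nd),
    n_edges = nrow(net$edges),
    n_unique_partners = length(partner_acc),
    n_domain_families = n_fam,
    n_core_edges = sum(net$edges$layer == "core"),
    n_global_edges = sum(net$edges$layer == "global")
  ), class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat(sprintf(paste0("nodes: %d\nedges: %d (core %d, global %d)\n",
                     "unique non-histone partners: %d\n"),
              x$n_nodes, x$n_edges, x$n_core_edges, x$n_global_edges,
              x$n_unique_partners))
  if (!is.na(x$n_domain_families))
    cat(sprintf("domain families: %d\n", x$n_domain_families))
  invisible(x)
}
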