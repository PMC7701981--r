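# Network serialization in open graph formats, plus pipeline config.
#
# GraphML and JSON graph are lossless (read . write is the identity on
# nodes, edges, layers and evidence); SIF and edge TSV are documented
# one-way exports. All set-like output is serialized in lexicographic
# (bytewise) order and no file contains wall-clock content, so repeated
# runs are byte-identical.

NETWORK_FORMATS <- c("graphml", "sif", "edge_tsv", "json_graph")

format_from_path <- function(path) {
  switch(tolower(tools::file_ext(path)),
         graphml = "graphml", sif = "sif", json = "json_graph",
         tsv = "edge_tsv",
         stop("cannot infer network format from extension: ", path))
}

serialize_evidence <- function(evl) {
  as.character(jsonlite::toJSON(lapply(evl, unclass), auto_unbox = TRUE,
                                digits = NA))
}

deserialize_evidence <- function(s) {
  if (is.na(s) || !nzchar(s)) return(list())
  lst <- jsonlite::fromJSON(s, simplifyVector = FALSE)
  lapply(lst, function(ev)
    evidence_item(ev$source_kind, ev$source_id,
                  lapply(ev$attributes %||% list(), identity)))
}

#' Write a network to an open graph format
#'
#' `graphml` and `json_graph` are lossless round-trip formats (evidence
#' is embedded as a JSON edge attribute in GraphML). `sif` writes
#' Cytoscape simple-interaction lines (`A <layer> B`, isolated nodes on
#' their own line) and `edge_tsv` a flat edge table with evidence
#' summaries; both are lossy one-way exports.
#'
#' @param net an [interaction_network()]; must pass [validate_network()].
#' @param dest output file path.
#' @param format one of `"graphml"`, `"sif"`, `"edge_tsv"`,
#'   `"json_graph"`; default inferred from the file extension
#'   (`.graphml`, `.sif`, `.tsv`, `.json`).
#' @return `dest`, invisibly.
#' @export
write_network <- function(net, dest, format = NULL) {
  stopifnot(inherits(net, "interaction_network"))
  if (is.null(format)) format <- format_from_path(dest)
  format <- match.arg(format, NETWORK_FORMATS)
  viol <- validate_network(net)
  if (nrow(viol))
    stop("write_network: refusing to serialize an invalid network (",
         nrow(viol), " violation(s), first: ", viol$rule[1], " ",
         viol$detail[1], ")")
  switch(format,
    graphml = write_network_graphml(net, dest),
    json_graph = write_network_json(net, dest),
    sif = write_network_sif(net, dest),
    edge_tsv = write_network_edge_tsv(net, dest))
  invisible(dest)
}

#' Read a network written by [write_network()]
#'
#' Only the lossless formats can be read back.
#'
#' @param path file path.
#' @param format `"graphml"` or `"json_graph"`; default inferred from
#'   the extension.
#' @return an [interaction_network()].
#' @export
read_network <- function(path, format = NULL) {
  if (is.null(format)) format <- format_from_path(path)
  format <- match.arg(format, c("graphml", "json_graph"))
  switch(format,
    graphml = read_network_graphml(path),
    json_graph = read_network_json(path))
}

write_network_graphml <- function(net, dest) {
  nd <- net$nodes
  if (nrow(nd) == 0) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    g <- igraph::make_empty_graph(nrow(nd), directed = FALSE)
    igraph::V(g)$name <- nd$id
    for (col in setdiff(names(nd), "id")) {
      # attributes go out as strings ("" = NA); the granularity schema
      # restores types on read
      v <- as.character(nd[[col]])
      v[is.na(v)] <- ""
      # "name" is igraph's node-id slot; store the display name as label
      attr_name <- if (col == "name") "label" else col
      g <- igraph::set_vertex_attr(g, attr_name, value = v)
    }
    if (nrow(net$edges)) {
      idx <- rbind(match(net$edges$node_a, nd$id),
                   match(net$edges$node_b, nd$id))
      g <- igraph::add_edges(g, as.vector(idx))
      g <- igraph::set_edge_attr(g, "layer", value = net$edges$layer)
      g <- igraph::set_edge_attr(g, "evidence_json",
        value = vapply(net$evidence, serialize_evidence, character(1)))
    }
  }
  g <- igraph::set_graph_attr(g, "granularity", net$granularity)
  g <- igraph::set_graph_attr(g, "provenance_json",
    as.character(jsonlite::toJSON(net$provenance, auto_unbox = TRUE,
                                  digits = NA)))
  igraph::write_graph(g, dest, format = "graphml")
  invisible(dest)
}

read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  granularity <- igraph::graph_attr(g, "granularity") %||% "protein"
  prov <- tryCatch(
    jsonlite::fromJSON(igraph::graph_attr(g, "provenance_json") %||% "{}",
                       simplifyVector = TRUE),
    error = function(e) list())
  schema <- node_schema(granularity)
  n <- igraph::vcount(g)
  nodes <- data.frame(id = if (n) igraph::V(g)$name else character(),
                      stringsAsFactors = FALSE)
  for (col in setdiff(names(schema), "id")) {
    attr_name <- if (col == "name") "label" else col
    if (!attr_name %in% igraph::vertex_attr_names(g)) next
    v <- as.character(igraph::vertex_attr(g, attr_name))
    v[v %in% ""] <- NA
    nodes[[col]] <- switch(schema[[col]],
                           character = as.character(v),
                           integer = as.integer(v),
                           logical = as.logical(v))
  }
  ne <- igraph::ecount(g)
  if (ne) {
    ends <- igraph::as_edgelist(g, names = TRUE)
    edges <- data.frame(node_a = ends[, 1], node_b = ends[, 2],
                        layer = igraph::edge_attr(g, "layer") %||%
                          rep("core", ne),
                        stringsAsFactors = FALSE)
    ev_json <- igraph::edge_attr(g, "evidence_json")
    edges$evidence <- I(if (is.null(ev_json)) rep(list(list()), ne)
                        else lapply(ev_json, deserialize_evidence))
  } else {
    edges <- NULL
  }
  interaction_network(nodes, edges, granularity, provenance = as.list(prov))
}

write_network_json <- function(net, dest) {
  obj <- list(
    format = "histonet-json-graph",
    version = 1L,
    granularity = net$granularity,
    provenance = net$provenance,
    nodes = net$nodes,
    edges = cbind(net$edges,
                  data.frame(evidence = I(lapply(net$evidence,
                                                 function(e)
                                                   lapply(e, unclass))))))
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                           na = "null", pretty = TRUE, dataframe = "rows")
  writeLines(json, dest)
  invisible(dest)
}

read_network_json <- function(path) {
  obj <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                            simplifyVector = FALSE)
  if (!identical(obj$format, "histonet-json-graph"))
    stop("not a histonet JSON graph file: ", path)
  granularity <- obj$granularity
  schema <- node_schema(granularity)
  nodes <- data.frame(id = vapply(obj$nodes, function(x)
    as.character(x$id), character(1)), stringsAsFactors = FALSE)
  for (col in setdiff(names(schema), "id")) {
    v <- lapply(obj$nodes, function(x) x[[col]])
    v <- vapply(v, function(x)
      if (is.null(x)) NA_character_ else as.character(x), character(1))
    nodes[[col]] <- switch(schema[[col]],
                           character = v,
                           integer = as.integer(v),
                           logical = as.logical(v))
  }
  if (length(obj$edges)) {
    edges <- data.frame(
      node_a = vapply(obj$edges, function(e) as.character(e$node_a),
                      character(1)),
      node_b = vapply(obj$edges, function(e) as.character(e$node_b),
                      character(1)),
      layer = vapply(obj$edges, function(e)
        as.character(e$layer %||% "core"), character(1)),
      stringsAsFactors = FALSE)
    edges$evidence <- I(lapply(obj$edges, function(e)
      lapply(e$evidence %||% list(), function(ev)
        evidence_item(ev$source_kind, ev$source_id,
                      lapply(ev$attributes %||% list(), identity)))))
  } else edges <- NULL
  interaction_network(nodes, edges, granularity,
                      provenance = as.list(obj$provenance %||% list()))
}

write_network_sif <- function(net, dest) {
  e <- net$edges
  lines <- sprintf("%s\t%s\t%s", e$node_a, e$layer, e$node_b)
  isolated <- setdiff(net$nodes$id, c(e$node_a, e$node_b))
  lines <- c(lines, sort(isolated, method = "radix"))
  writeLines(lines, dest)
  invisible(dest)
}

write_network_edge_tsv <- function(net, dest) {
  e <- net$edges
  df <- data.frame(
    node_a = e$node_a, node_b = e$node_b, layer = e$layer,
    n_evidence = vapply(net$evidence, length, integer(1)),
    source_kinds = vapply(net$evidence, function(evl)
      paste(sort(unique(vapply(evl, `[[`, character(1), "source_kind")),
                 method = "radix"), collapse = ";"), character(1)),
    source_ids = vapply(net$evidence, function(evl)
      paste(sort(vapply(evl, `[[`, character(1), "source_id"),
                 method = "radix"), collapse = ";"), character(1)),
    stringsAsFactors = FALSE)
  write_tsv_plain(df, dest)
  invisible(dest)
}

#' Write the node table of a network to TSV
#' @param net an [interaction_network()].
#' @param dest output path.
#' @return `dest`, invisibly.
#' @export
write_node_table <- function(net, dest) {
  write_tsv_plain(net$nodes, dest)
  invisible(dest)
}

# ---- pipeline configuration --------------------------------------------

#' Default pipeline configuration
#'
#' @return named list of pipeline parameters: `cutoff` (heavy-atom
#'   contact cutoff in Angstrom, 5.0), `focal_taxon` (9606, human),
#'   `assembly_policy`, `binary_method_codes`, `conserved_partner_map`
#'   and `log_level`.
#' @export
default_config <- function() {
  list(cutoff = 5.0,
       focal_taxon = 9606L,
       assembly_policy = "first_assembly",
       binary_method_codes = default_binary_methods(),
       conserved_partner_map = list(),
       seed = 1L,
       log_level = "info")
}

#' Read a YAML pipeline configuration
#'
#' Keys missing from the file take their [default_config()] values;
#' unknown keys are an error (they are usually typos).
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return configuration list.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in names(user)) cfg[[k]] <- user[[k]]
  cfg$cutoff <- as.numeric(cfg$cutoff)
  if (!isTRUE(cfg$cutoff > 0)) stop("config: cutoff must be > 0")
  cfg$focal_taxon <- as.integer(cfg$focal_taxon)
  cfg
}
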