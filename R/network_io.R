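#' Export a ceRNA network
#'
#' Three formats are supported. `sif` is the simple interaction format read
#' by Cytoscape: one edge per line, `source<TAB>type<TAB>target`, with edge
#' types `binds` (lncRNA to sponged miRNA), `induces` (lncRNA to induced
#' miRNA) and `targets` (miRNA to mRNA); node attributes are not carried.
#' `graphml` and `json` carry all node and edge attributes and round-trip
#' through [read_network()] exactly.
#'
#' @param network A `CeRNANetwork`.
#' @param path Output file path.
#' @param format One of `"SIF"`, `"GraphML"`, `"JSON"` (case-insensitive).
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("SIF", "GraphML", "JSON")) {
  stopifnot(inherits(network, "CeRNANetwork"))
  if (length(format) == 1L && !format %in% c("SIF", "GraphML", "JSON")) {
    fmt <- tolower(format)
    if (!fmt %in% c("sif", "graphml", "json"))
      stop("unknown network format: ", format, call. = FALSE)
  } else fmt <- tolower(match.arg(format))

  if (fmt == "sif") {
    e <- network$edges
    writeLines(if (nrow(e)) paste(e$from, e$interaction, e$to, sep = "\t")
               else character(0), path)
  } else if (fmt == "json") {
    jsonlite::write_json(
      list(lncrna_id = network$lncrna_id,
           nodes = network$nodes, edges = network$edges),
      path, dataframe = "columns", auto_unbox = TRUE, digits = NA,
      na = "null", pretty = TRUE)
  } else {
    g <- network_to_igraph(network)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a ceRNA network written by [write_network()]
#'
#' @param path File path.
#' @param format `"GraphML"` or `"JSON"` (SIF does not carry attributes and
#'   is write-only).
#' @return A `CeRNANetwork`.
#' @export
read_network <- function(path, format = c("GraphML", "JSON")) {
  fmt <- tolower(match.arg(format))
  if (fmt == "json") {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    nodes <- as_node_frame(raw$nodes)
    edges <- as_edge_frame(raw$edges)
    return(cerna_network(nodes, edges, raw$lncrna_id))
  }
  g <- igraph::read_graph(path, format = "graphml")
  igraph_to_network(g)
}

node_cols <- c("id", "node_type", "classification", "signed_fc_kd1",
               "signed_fc_kd2", "binding_score", "common_target_count")
node_num <- c("signed_fc_kd1", "signed_fc_kd2", "binding_score",
              "common_target_count")

as_node_frame <- function(x) {
  if (is.null(x) || !length(x) || (is.list(x) && !length(x[["id"]]))) {
    out <- data.frame(id = character(0), node_type = character(0),
                      classification = character(0),
                      signed_fc_kd1 = numeric(0), signed_fc_kd2 = numeric(0),
                      binding_score = numeric(0),
                      common_target_count = numeric(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out <- as.data.frame(x, stringsAsFactors = FALSE)[, node_cols]
  for (col in node_num) out[[col]] <- as.numeric(out[[col]])
  out
}

as_edge_frame <- function(x) {
  if (is.null(x) || !length(x) || (is.list(x) && !length(x[["from"]])))
    return(data.frame(from = character(0), interaction = character(0),
                      to = character(0), stringsAsFactors = FALSE))
  as.data.frame(x, stringsAsFactors = FALSE)[, c("from", "interaction", "to")]
}

network_to_igraph <- function(network) {
  nodes <- network$nodes
  vdf <- data.frame(name = nodes$id, nodes[, setdiff(node_cols, "id")],
                    stringsAsFactors = FALSE)
  edf <- if (nrow(network$edges))
    network$edges[, c("from", "to", "interaction")]
  else data.frame(from = character(0), to = character(0),
                  interaction = character(0))
  g <- igraph::graph_from_data_frame(edf, directed = TRUE, vertices = vdf)
  igraph::graph_attr(g, "lncrna_id") <- network$lncrna_id
  g
}

igraph_to_network <- function(g) {
  va <- igraph::vertex_attr(g)
  nodes <- data.frame(id = va$name, node_type = va$node_type,
                      classification = va$classification,
                      stringsAsFactors = FALSE)
  for (col in node_num) {
    v <- as.numeric(va[[col]])
    v[is.nan(v)] <- NA_real_   # igraph serializes NA numerics as NaN
    nodes[[col]] <- v
  }
  el <- igraph::as_edgelist(g)
  edges <- data.frame(
    from = as.character(el[, 1]),
    interaction = as.character(igraph::edge_attr(g, "interaction")
                               %||% character(0)),
    to = as.character(el[, 2]), stringsAsFactors = FALSE)
  cerna_network(nodes, edges, igraph::graph_attr(g, "lncrna_id"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
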