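#' Pathway graphs
#'
#' A `pathway_graph` is the in-memory form of one species-specific pathway:
#' an undirected simple graph whose nodes are pathway members (genes,
#' compounds, or members lifted out of KGML group entries).  Node identity is
#' local to the graph (integer `node_id`); identity *across* species lives in
#' the `member_ids` attached to each node, so that module overlap between two
#' species is a plain set intersection of member identifiers.
#'
#' @param nodes data frame with columns `node_id` (unique integers),
#'   `node_class` (one of `"gene"`, `"compound"`, `"group-derived"`) and a
#'   list column `member_ids` of non-empty character vectors (may be empty
#'   for compound nodes only when the compound carries its KGML name, which
#'   always exists in practice; gene-class nodes must have members).
#' @param edges data frame with integer columns `from`, `to` and an optional
#'   character column `subtype` carrying the KGML relation subtype tag.
#'   Self-loops are dropped and duplicate edges collapsed (first subtype
#'   kept): all downstream computations assume a simple graph.
#' @param species short species code (KEGG-style, e.g. `"hsa"`).
#' @return an object of class `pathway_graph`.
#' @examples
#' g <- pathway_graph(
#'   nodes = data.frame(node_id = 1:3, node_class = "gene"),
#'   edges = data.frame(from = c(1, 2), to = c(2, 3)),
#'   species = "toy"
#' )
#' max_total_degree(g)
#' @export
pathway_graph <- function(nodes, edges = NULL, species = "unknown") {
  if (is.null(nodes) || nrow(as.data.frame(nodes)) == 0L) {
    nodes <- data.frame(node_id = integer(0), node_class = character(0))
    nodes$member_ids <- list()
  }
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (!all(c("node_id", "node_class") %in% names(nodes))) {
    stop("`nodes` needs columns node_id and node_class", call. = FALSE)
  }
  nodes$node_id <- as.integer(nodes$node_id)
  if (anyDuplicated(nodes$node_id)) {
    stop("duplicate node_id in `nodes`: ",
         paste(unique(nodes$node_id[duplicated(nodes$node_id)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(nodes$node_class), c("gene", "compound", "group-derived"))
  if (length(bad)) {
    stop("unknown node_class: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(nodes$member_ids)) {
    # default: each node is its own member, named after its id
    nodes$member_ids <- lapply(nodes$node_id, function(i) paste0("n", i))
  }
  nodes$member_ids <- unname(lapply(nodes$member_ids, as.character))
  empty <- vapply(nodes$member_ids, length, 1L) == 0L & nodes$node_class == "gene"
  if (any(empty)) {
    stop("gene-class nodes with empty member_ids: ",
         paste(nodes$node_id[empty], collapse = ", "), call. = FALSE)
  }

  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    edges <- data.frame(from = integer(0), to = integer(0),
                        subtype = character(0), stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (is.null(edges$subtype)) edges$subtype <- NA_character_
    edges$from <- as.integer(edges$from)
    edges$to <- as.integer(edges$to)
    unknown <- setdiff(c(edges$from, edges$to), nodes$node_id)
    if (length(unknown)) {
      stop("edge endpoints not in nodes: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    # canonicalize to a simple graph
    lo <- pmin(edges$from, edges$to)
    hi <- pmax(edges$from, edges$to)
    keep <- lo != hi & !duplicated(paste(lo, hi))
    edges <- data.frame(from = lo[keep], to = hi[keep],
                        subtype = as.character(edges$subtype)[keep],
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  nodes <- nodes[order(nodes$node_id), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(species = as.character(species),
                 nodes = nodes[c("node_id", "node_class", "member_ids")],
                 edges = edges),
            class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("<pathway_graph> species '%s': %d nodes, %d edges\n",
              x$species, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

n_nodes <- function(graph) nrow(graph$nodes)
n_edges <- function(graph) nrow(graph$edges)

#' Convert a pathway graph to an igraph object
#'
#' Vertex names are the character form of `node_id`.
#' @param graph a [pathway_graph()].
#' @return an undirected [igraph::graph] object.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  ids <- as.character(graph$nodes$node_id)
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (nrow(graph$edges)) {
    g <- igraph::add_edges(g, rbind(match(graph$edges$from, graph$nodes$node_id),
                                    match(graph$edges$to, graph$nodes$node_id)))
  }
  g
}

# adjacency list keyed by node_id (character); values are integer node ids
adjacency_list <- function(graph) {
  ids <- graph$nodes$node_id
  adj <- vector("list", length(ids))
  names(adj) <- as.character(ids)
  if (nrow(graph$edges)) {
    for (k in seq_len(nrow(graph$edges))) {
      a <- graph$edges$from[k]; b <- graph$edges$to[k]
      adj[[as.character(a)]] <- c(adj[[as.character(a)]], b)
      adj[[as.character(b)]] <- c(adj[[as.character(b)]], a)
    }
  }
  adj
}

#' Total degree of one node
#'
#' The number of distinct neighbours of `node_id`; pathway graphs are simple
#' and undirected, so this is the count of incident edges.
#'
#' @param graph a [pathway_graph()].
#' @param node_id node identifier present in the graph.
#' @return non-negative integer.
#' @export
total_degree <- function(graph, node_id) {
  stopifnot(inherits(graph, "pathway_graph"))
  node_id <- as.integer(node_id)
  if (!node_id %in% graph$nodes$node_id) {
    stop("unknown node_id: ", node_id, call. = FALSE)
  }
  sum(graph$edges$from == node_id) + sum(graph$edges$to == node_id)
}

# degrees of all nodes, named by node_id
degree_vector <- function(graph) {
  ids <- graph$nodes$node_id
  d <- integer(length(ids))
  names(d) <- as.character(ids)
  if (nrow(graph$edges)) {
    t1 <- table(factor(graph$edges$from, levels = ids))
    t2 <- table(factor(graph$edges$to, levels = ids))
    d <- as.integer(t1 + t2)
    names(d) <- as.character(ids)
  }
  d
}

#' Highest total degree in a graph
#'
#' Upper bound of the legal range of the modularization factor `c`.
#' Returns 0 for a node-free or edge-free graph.
#'
#' @param graph a [pathway_graph()].
#' @return non-negative integer.
#' @export
max_total_degree <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  if (nrow(graph$edges) == 0L) return(0L)
  max(degree_vector(graph))
}

#' Connected components of a pathway graph
#'
#' @param graph a [pathway_graph()].
#' @return list of integer vectors of node ids, each sorted; components
#'   ordered by their smallest node id.
#' @export
connected_components <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  if (nrow(graph$nodes) == 0L) return(list())
  comp <- igraph::components(as_igraph(graph))
  ids <- graph$nodes$node_id
  parts <- split(ids, comp$membership)
  parts <- lapply(parts, function(v) sort(as.integer(v)))
  unname(parts[order(vapply(parts, min, 1L))])
}

#' Write / read the package's plain-text graph interchange format
#'
#' Two tab-separated tables: a node table (`node_id`, `node_class`,
#' `member_ids` comma-joined) and an edge list (`node1`, `node2`,
#' `subtype`).
#'
#' @param graph a [pathway_graph()].
#' @param node_file,edge_file file paths.
#' @return `write_graph_tables()` returns the paths invisibly;
#'   `read_graph_tables()` returns a [pathway_graph()].
#' @export
write_graph_tables <- function(graph, node_file, edge_file) {
  stopifnot(inherits(graph, "pathway_graph"))
  nt <- data.frame(node_id = graph$nodes$node_id,
                   node_class = graph$nodes$node_class,
                   member_ids = vapply(graph$nodes$member_ids,
                                       paste, "", collapse = ","),
                   stringsAsFactors = FALSE)
  utils::write.table(nt, node_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  et <- data.frame(node1 = graph$edges$from, node2 = graph$edges$to,
                   subtype = graph$edges$subtype, stringsAsFactors = FALSE)
  utils::write.table(et, edge_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(node_file, edge_file))
}

#' @rdname write_graph_tables
#' @param species species code for the reconstructed graph.
#' @export
read_graph_tables <- function(node_file, edge_file, species = "unknown") {
  nt <- utils::read.table(node_file, sep = "\t", header = TRUE,
                          colClasses = c("integer", "character", "character"))
  nt$member_ids <- strsplit(nt$member_ids, ",", fixed = TRUE)
  et <- utils::read.table(edge_file, sep = "\t", header = TRUE,
                          colClasses = c("integer", "integer", "character"))
  pathway_graph(nodes = nt,
                edges = data.frame(from = et$node1, to = et$node2,
                                   subtype = et$subtype),
                species = species)
}
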