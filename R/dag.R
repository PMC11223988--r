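# Directed acyclic graph over named nodes; igraph backs the graph
# algorithms, the object itself stays a light S3 list.

#' Directed acyclic graph over named nodes
#'
#' @param nodes character vector of node names.
#' @param edges two-column matrix or data.frame of (parent, child) pairs;
#'   `NULL` for the empty graph.
#' @return An object of class `mf_dag` with fields `nodes` and `edges`
#'   (a character matrix with columns `from`, `to`).
#' @export
bn_dag <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names")
  if (is.null(edges) || NROW(edges) == 0) {
    edges <- matrix(character(0), ncol = 2,
                    dimnames = list(NULL, c("from", "to")))
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2) stop("edges must have two columns (parent, child)")
    dimnames(edges) <- list(NULL, c("from", "to"))
    storage.mode(edges) <- "character"
  }
  dag <- structure(list(nodes = nodes, edges = edges), class = "mf_dag")
  validate_dag(dag)
  dag
}

validate_dag <- function(dag) {
  e <- dag$edges
  if (nrow(e)) {
    bad <- !(e %in% dag$nodes)
    if (any(bad)) stop("edge endpoint(s) not declared as nodes: ",
                       paste(unique(e[bad]), collapse = ", "))
    if (any(e[, 1] == e[, 2])) stop("self-loop edges are not allowed")
    if (anyDuplicated(paste(e[, 1], e[, 2], sep = "\r")))
      stop("duplicate edges")
  }
  if (!igraph::is_dag(as_igraph(dag)))
    stop("graph contains a directed cycle")
  invisible(dag)
}

as_igraph <- function(dag) {
  igraph::graph_from_data_frame(
    as.data.frame(dag$edges, stringsAsFactors = FALSE),
    directed = TRUE, vertices = dag$nodes)
}

#' @rdname bn_dag
#' @param dag an `mf_dag`.
#' @param node a node name.
#' @export
dag_parents <- function(dag, node) {
  unname(dag$edges[dag$edges[, 2] == node, 1])
}

#' @rdname bn_dag
#' @export
dag_children <- function(dag, node) {
  unname(dag$edges[dag$edges[, 1] == node, 2])
}

#' @rdname bn_dag
#' @export
dag_topo_sort <- function(dag) {
  names(igraph::topo_sort(as_igraph(dag), mode = "out"))
}

# all strict ancestors of any node in `nodes`
dag_ancestors <- function(dag, nodes) {
  g <- as_igraph(dag)
  anc <- unique(unlist(lapply(nodes, function(v)
    names(igraph::subcomponent(g, v, mode = "in")))))
  setdiff(anc, nodes)
}

dag_add_edge <- function(dag, from, to) {
  bn_dag(dag$nodes, rbind(dag$edges, c(from, to)))
}

dag_degree <- function(dag) {
  deg <- stats::setNames(integer(length(dag$nodes)), dag$nodes)
  if (nrow(dag$edges)) {
    t1 <- table(dag$edges[, 1]); t2 <- table(dag$edges[, 2])
    deg[names(t1)] <- deg[names(t1)] + as.integer(t1)
    deg[names(t2)] <- deg[names(t2)] + as.integer(t2)
  }
  deg
}

#' Assign flow-model layers by longest path from a source
#'
#' A node's layer is 1 plus the length (edge count) of the longest
#' directed path reaching it from any source node, so every edge points
#' from a strictly lower to a strictly higher layer. Nodes with no edges
#' at all are excluded from the flow model (no layer), mirroring how
#' disconnected variables are dropped from the reported model.
#'
#' @param x an `mf_dag` or `mf_bn`.
#' @return Object of class `mf_layers`: list with `layers` (named integer,
#'   connected nodes only), `n_layers`, and `excluded` (degree-0 nodes).
#' @export
assign_layers <- function(x) {
  dag <- if (inherits(x, "mf_bn")) x$dag else x
  stopifnot(inherits(dag, "mf_dag"))
  deg <- dag_degree(dag)
  excluded <- names(deg)[deg == 0]
  keep <- setdiff(dag$nodes, excluded)
  layers <- stats::setNames(integer(0), character(0))
  if (length(keep)) {
    sub <- bn_dag(keep, dag$edges)
    layers <- stats::setNames(rep(1L, length(keep)), keep)
    for (v in dag_topo_sort(sub)) {
      pa <- dag_parents(sub, v)
      if (length(pa)) layers[v] <- 1L + max(layers[pa])
    }
  }
  structure(list(layers = layers,
                 n_layers = if (length(layers)) max(layers) else 0L,
                 excluded = excluded),
            class = "mf_layers")
}

#' @export
print.mf_layers <- function(x, ...) {
  cat("Flow-model layering:", x$n_layers, "layers,",
      length(x$excluded), "excluded node(s)\n")
  for (l in seq_len(x$n_layers))
    cat(sprintf("  layer %d: %s\n", l,
                paste(sort(names(x$layers)[x$layers == l]), collapse = ", ")))
  if (length(x$excluded))
    cat("  excluded:", paste(sort(x$excluded), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.mf_dag <- function(x, ...) {
  cat("DAG:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}
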