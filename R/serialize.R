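# Model serialization: a self-contained JSON document (nodes, states,
# edges, CPTs with explicit parent-state ordering, metadata) and a
# Graphviz DOT export of the flow model with edge-probability labels.

#' Serialize a network to JSON
#'
#' The document records node order, state order, edges, and every CPT as
#' a row-major (parent configuration by state) matrix together with its
#' parent ordering, so deserialization reproduces the network exactly.
#' Output is deterministic: the same network always yields the same
#' bytes.
#'
#' @param bn an `mf_bn`.
#' @param path file to write, or `NULL` to return the JSON string.
#' @return JSON string (invisibly when written to a file).
#' @export
bn_to_json <- function(bn, path = NULL) {
  doc <- list(
    nodes = lapply(bn$dag$nodes, function(v) {
      nd <- list(name = v, states = bn$states[[v]])
      if (!is.null(bn$categories)) nd$category <- bn$categories[[v]]
      if (!is.null(bn$display)) nd$display <- bn$display[[v]]
      nd
    }),
    edges = unname(apply(bn$dag$edges, 1, function(r) as.list(unname(r)))),
    cpts = lapply(bn$cpts, function(cpt) {
      list(parents = I(cpt$parents),
           prob = lapply(seq_len(nrow(cpt$prob)),
                         function(i) unname(cpt$prob[i, ])))
    })
  )
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Deserialize a network from JSON
#'
#' @param x path to a JSON file, or a JSON string produced by
#'   [bn_to_json()].
#' @return An `mf_bn`.
#' @export
bn_from_json <- function(x) {
  doc <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  nodes <- vapply(doc$nodes, `[[`, "", "name")
  states <- lapply(doc$nodes, function(nd) unlist(nd$states))
  names(states) <- nodes
  edges <- if (length(doc$edges))
    do.call(rbind, lapply(doc$edges, unlist)) else NULL
  dag <- bn_dag(nodes, edges)
  cpts <- lapply(nodes, function(v) {
    entry <- doc$cpts[[v]]
    pa <- unlist(entry$parents) %||% character(0)
    prob <- do.call(rbind, lapply(entry$prob, unlist))
    bn_cpt(v, states[[v]], prob, parents = pa, parent_states = states[pa])
  })
  cats <- vapply(doc$nodes, function(nd) nd$category %||% NA_character_, "")
  disp <- vapply(doc$nodes, function(nd) nd$display %||% NA_character_, "")
  discrete_bn(dag, cpts,
              categories = if (!all(is.na(cats)))
                stats::setNames(cats, nodes),
              display = if (!all(is.na(disp)))
                stats::setNames(disp, nodes))
}

#' Export a network as a Graphviz DOT graph
#'
#' Nodes are grouped by category (when known) with distinct shapes, and
#' each edge is labelled with its annotation probability
#' (see [edge_probabilities()]): P(child present | parent state), one
#' label per non-reference parent state.
#'
#' @param bn an `mf_bn`.
#' @param path file to write, or `NULL` to return the DOT text.
#' @param edge_labels label edges with conditional probabilities.
#' @return DOT source as a character string (invisibly when written).
#' @export
bn_to_dot <- function(bn, path = NULL, edge_labels = TRUE) {
  shape_for <- c(event = "box", attributional = "ellipse",
                 system = "diamond", conditional = "ellipse",
                 knowledge_behavioral = "oval")
  lines <- c("digraph flow_model {", "  rankdir=TB;")
  for (v in bn$dag$nodes) {
    lab <- if (!is.null(bn$display)) bn$display[[v]] else v
    shape <- if (!is.null(bn$categories))
      shape_for[[bn$categories[[v]]]] else "ellipse"
    lines <- c(lines, sprintf('  "%s" [label="%s", shape=%s];', v, lab, shape))
  }
  if (nrow(bn$dag$edges)) {
    ep <- if (edge_labels) edge_probabilities(bn) else NULL
    for (i in seq_len(nrow(bn$dag$edges))) {
      from <- bn$dag$edges[i, 1]; to <- bn$dag$edges[i, 2]
      attr_txt <- ""
      if (!is.null(ep)) {
        sub <- ep[ep$from == from & ep$to == to, , drop = FALSE]
        lab <- if (nrow(sub) == 1) sprintf("%.2f", sub$prob) else
          paste(sprintf("%s: %.2f", sub$from_state, sub$prob),
                collapse = "\\n")
        attr_txt <- sprintf(' [label="%s"]', lab)
      }
      lines <- c(lines, sprintf('  "%s" -> "%s"%s;', from, to, attr_txt))
    }
  }
  lines <- c(lines, "}")
  txt <- paste(lines, collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
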