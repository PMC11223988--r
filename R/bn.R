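# Discrete Bayesian network: DAG + one conditional probability table per
# node. CPT rows enumerate parent configurations in expand.grid order
# (first parent varying fastest); columns are the node's states.

#' Conditional probability table for one node
#'
#' @param node node name.
#' @param states character vector of the node's states.
#' @param parents character vector of parent names (may be empty).
#' @param parent_states named list of state vectors, one per parent.
#' @param prob numeric matrix, `prod(lengths(parent_states))` rows (parent
#'   configurations in expand.grid order, first parent varying fastest) by
#'   `length(states)` columns; each row must sum to 1 within 1e-9.
#' @return Object of class `mf_cpt`.
#' @export
bn_cpt <- function(node, states, prob, parents = character(),
                   parent_states = list()) {
  prob <- rbind(prob)
  stopifnot(length(parents) == length(parent_states))
  if (length(parents)) names(parent_states) <- parents
  q <- prod(vapply(parent_states, length, 0L), 1L)
  if (nrow(prob) != q)
    stop(sprintf("CPT for '%s': %d rows but %d parent configurations",
                 node, nrow(prob), q))
  if (ncol(prob) != length(states))
    stop(sprintf("CPT for '%s': %d columns but %d states",
                 node, ncol(prob), length(states)))
  if (any(prob < -1e-12 | prob > 1 + 1e-12))
    stop(sprintf("CPT for '%s': entries outside [0, 1]", node))
  if (any(abs(rowSums(prob) - 1) > 1e-9))
    stop(sprintf("CPT for '%s': rows must sum to 1", node))
  dimnames(prob) <- list(NULL, states)
  structure(list(node = node, states = states, parents = parents,
                 parent_states = parent_states,
                 prob = pmin(pmax(prob, 0), 1)),
            class = "mf_cpt")
}

# row index into a CPT from integer parent state codes (matrix n x p)
cpt_row_index <- function(cpt, parent_codes) {
  if (!length(cpt$parents)) return(rep(1L, max(NROW(parent_codes), 1L)))
  parent_codes <- cbind(parent_codes)
  idx <- rep(1L, nrow(parent_codes))
  stride <- 1L
  for (j in seq_along(cpt$parents)) {
    idx <- idx + (parent_codes[, j] - 1L) * stride
    stride <- stride * length(cpt$parent_states[[j]])
  }
  idx
}

#' Discrete Bayesian network
#'
#' Bundles a DAG with one CPT per node; CPT parent sets must equal the
#' DAG parent sets node by node. Optional `categories` (named character)
#' and `display` (named character) carry codebook metadata through
#' learning and reporting.
#'
#' @param dag an `mf_dag`.
#' @param cpts list of `mf_cpt`, one per node.
#' @param categories optional named character vector of node categories.
#' @param display optional named character vector of display labels.
#' @return Object of class `mf_bn`.
#' @export
discrete_bn <- function(dag, cpts, categories = NULL, display = NULL) {
  names(cpts) <- vapply(cpts, `[[`, "", "node")
  if (!setequal(names(cpts), dag$nodes))
    stop("CPTs must cover exactly the DAG nodes")
  cpts <- cpts[dag$nodes]
  for (v in dag$nodes) {
    if (!setequal(cpts[[v]]$parents, dag_parents(dag, v)))
      stop(sprintf("CPT parents for '%s' do not match the DAG", v))
  }
  structure(list(dag = dag, cpts = cpts,
                 states = lapply(cpts, `[[`, "states"),
                 categories = categories, display = display),
            class = "mf_bn")
}

#' @export
print.mf_bn <- function(x, ...) {
  cat("Discrete Bayesian network:", length(x$dag$nodes), "nodes,",
      nrow(x$dag$edges), "edges\n")
  invisible(x)
}

# assignment (named character) -> integer state codes in bn node order
assignment_codes <- function(bn, assignment) {
  nodes <- bn$dag$nodes
  miss <- setdiff(nodes, names(assignment))
  if (length(miss))
    stop("assignment is missing node(s): ", paste(miss, collapse = ", "))
  codes <- vapply(nodes, function(v) {
    k <- match(assignment[[v]], bn$states[[v]])
    if (is.na(k))
      stop(sprintf("illegal state '%s' for node '%s'", assignment[[v]], v))
    k
  }, 0L)
  codes
}

#' Joint probability of a complete assignment
#'
#' Product over nodes of the CPT entry for the node's state given its
#' parents' states — the factorization the network encodes.
#'
#' @param bn an `mf_bn`.
#' @param assignment named character vector or list mapping every node to
#'   one of its states.
#' @return A probability in `[0, 1]`.
#' @export
bn_joint_probability <- function(bn, assignment) {
  codes <- assignment_codes(bn, unlist(assignment))
  p <- 1
  for (v in bn$dag$nodes) {
    cpt <- bn$cpts[[v]]
    row <- cpt_row_index(cpt, rbind(codes[cpt$parents]))
    p <- p * cpt$prob[row, codes[[v]]]
  }
  unname(p)
}

#' Exhaustive joint distribution (test oracle)
#'
#' Enumerates every complete assignment with its probability. Guarded to
#' state spaces of at most 2^20 cells; intended as a brute-force oracle
#' for small networks, not as a production inference path.
#'
#' @param bn an `mf_bn`.
#' @return data.frame with one character column per node plus `prob`.
#' @export
bn_enumerate_joint <- function(bn) {
  sizes <- vapply(bn$states, length, 0L)
  if (prod(sizes) > 2^20)
    stop("state space too large to enumerate (", prod(sizes), " cells)")
  grid <- expand.grid(bn$states, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  codes <- mapply(function(col, st) match(col, st),
                  grid, bn$states[names(grid)])
  codes <- cbind(codes)
  p <- rep(1, nrow(grid))
  for (v in bn$dag$nodes) {
    cpt <- bn$cpts[[v]]
    row <- cpt_row_index(cpt, codes[, cpt$parents, drop = FALSE])
    p <- p * cpt$prob[cbind(row, codes[, v])]
  }
  grid$prob <- p
  grid
}

#' Ancestral sampling from a network
#'
#' Draws complete assignments by sampling each node from its CPT in
#' topological order. Reproducible for a fixed seed; the caller's RNG
#' state is left untouched.
#'
#' @param bn an `mf_bn`.
#' @param n number of samples (rows).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return data.frame of `n` sampled assignments (character columns).
#' @export
bn_sample <- function(bn, n, seed = NULL) {
  stopifnot(n >= 1)
  draw <- function() {
    nodes <- bn$dag$nodes
    codes <- matrix(NA_integer_, nrow = n, ncol = length(nodes),
                    dimnames = list(NULL, nodes))
    for (v in dag_topo_sort(bn$dag)) {
      cpt <- bn$cpts[[v]]
      rows <- cpt_row_index(cpt, codes[, cpt$parents, drop = FALSE])
      pr <- cpt$prob[rows, , drop = FALSE]
      cum <- pr %*% upper.tri(diag(ncol(pr)), diag = TRUE)
      u <- stats::runif(n)
      codes[, v] <- 1L + as.integer(rowSums(cum < u))
    }
    out <- as.data.frame(
      lapply(nodes, function(v) bn$states[[v]][codes[, v]]),
      stringsAsFactors = FALSE)
    names(out) <- nodes
    out
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Edge annotation probabilities for flow-model export
#'
#' For every edge X -> Y returns P(Y = present | X = x) computed by exact
#' inference on the full network (Y's other parents are marginalized),
#' one value per non-reference state x of X (the reference state is X's
#' first state, `absent` for binary factors). For a multi-state child,
#' "present" is taken to be its last (highest-band) state. These values
#' label the exported flow-model graph.
#'
#' @param bn an `mf_bn`.
#' @return data.frame with columns `from`, `to`, `from_state`, `prob`.
#' @export
edge_probabilities <- function(bn) {
  e <- bn$dag$edges
  rows <- lapply(seq_len(nrow(e)), function(i) {
    x <- e[i, 1]; y <- e[i, 2]
    child_present <- bn$states[[y]][length(bn$states[[y]])]
    non_ref <- bn$states[[x]][-1]
    data.frame(from = x, to = y, from_state = non_ref,
               prob = vapply(non_ref, function(s) {
                 ev <- stats::setNames(list(s), x)
                 unname(bn_posterior(bn, y, evidence = ev)[child_present])
               }, 0),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(from = character(0), to = character(0),
               from_state = character(0), prob = numeric(0))
  rownames(out) <- NULL
  out
}
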