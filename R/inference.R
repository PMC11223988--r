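# Exact inference by variable elimination. Factors are flat numeric
# vectors over the expand.grid of their variables (first variable varying
# fastest), which keeps the algebra simple and fast for the small
# treewidths of incident-report networks. Inference prunes barren nodes
# first: only ancestors of the query and evidence variables participate,
# so interventions or edits in unrelated parts of the network cannot
# perturb a posterior even at floating-point level.

f_new <- function(vars, states, val) {
  list(vars = vars, states = states[vars], val = as.numeric(val))
}

f_from_cpt <- function(cpt) {
  vars <- c(cpt$parents, cpt$node)
  states <- c(cpt$parent_states, stats::setNames(list(cpt$states), cpt$node))
  # prob matrix is (configs x states), column-major vectorization puts the
  # parent configurations (first parent fastest) before the node index
  f_new(vars, states, as.vector(cpt$prob))
}

f_dims <- function(f) vapply(f$states, length, 0L)

# condition on var = state, dropping var from the scope
f_reduce <- function(f, var, state) {
  vi <- match(var, f$vars)
  if (is.na(vi)) return(f)
  si <- match(state, f$states[[vi]])
  if (is.na(si)) stop(sprintf("illegal state '%s' for node '%s'", state, var))
  dims <- f_dims(f)
  arr <- array(f$val, dims)
  idx <- lapply(dims, seq_len)
  idx[[vi]] <- si
  val <- do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
  f_new(f$vars[-vi], f$states[-vi], as.vector(val))
}

f_sumout <- function(f, var) {
  vi <- match(var, f$vars)
  dims <- f_dims(f)
  if (length(dims) == 1L) return(f_new(character(0), list(), sum(f$val)))
  arr <- aperm(array(f$val, dims), c(vi, seq_along(dims)[-vi]))
  val <- colSums(matrix(arr, nrow = dims[vi]))
  f_new(f$vars[-vi], f$states[-vi], val)
}

f_multiply <- function(f, g) {
  if (!length(f$vars)) return(f_new(g$vars, g$states, f$val * g$val))
  if (!length(g$vars)) return(f_new(f$vars, f$states, f$val * g$val))
  uvars <- union(f$vars, g$vars)
  ustates <- c(f$states, g$states)[!duplicated(c(f$vars, g$vars))]
  names(ustates) <- uvars
  udims <- vapply(ustates, length, 0L)
  total <- prod(udims)
  cell <- seq_len(total) - 1L
  stride <- cumprod(c(1L, udims[-length(udims)]))
  codes <- lapply(seq_along(uvars), function(k)
    (cell %/% stride[k]) %% udims[k])
  names(codes) <- uvars
  lin_index <- function(h) {
    idx <- rep(1, total)
    s <- 1
    for (v in h$vars) {
      idx <- idx + codes[[v]] * s
      s <- s * length(h$states[[v]])
    }
    idx
  }
  f_new(uvars, ustates, f$val[lin_index(f)] * g$val[lin_index(g)])
}

f_product <- function(factors) Reduce(f_multiply, factors)

# min-fill elimination ordering over the interaction graph of the factor
# scopes; deterministic tie-break by node name
min_fill_order <- function(scopes, elim_vars) {
  nbr <- list()
  add_clique <- function(vs) {
    for (v in vs) nbr[[v]] <<- union(nbr[[v]] %||% character(0),
                                     setdiff(vs, v))
  }
  for (sc in scopes) add_clique(sc)
  order_out <- character(0)
  remaining <- sort(elim_vars)
  while (length(remaining)) {
    fill <- vapply(remaining, function(v) {
      ns <- intersect(nbr[[v]] %||% character(0), names(nbr))
      if (length(ns) < 2) return(0L)
      cnt <- 0L
      for (i in seq_len(length(ns) - 1)) for (j in (i + 1):length(ns))
        if (!(ns[j] %in% nbr[[ns[i]]])) cnt <- cnt + 1L
      cnt
    }, 0L)
    v <- remaining[which.min(fill)]   # ties: first in sorted name order
    ns <- nbr[[v]] %||% character(0)
    add_clique(ns)
    for (u in ns) nbr[[u]] <- setdiff(nbr[[u]], v)
    nbr[[v]] <- NULL
    remaining <- setdiff(remaining, v)
    order_out <- c(order_out, v)
  }
  order_out
}

#' Exact posterior distributions by variable elimination
#'
#' Computes the exact joint posterior of one or more query nodes given
#' evidence, by variable elimination with a min-fill ordering (ties
#' broken by node name) after pruning all nodes that are not ancestors of
#' the query or evidence. Evidence with probability zero under the model
#' raises an explicit "impossible evidence" error rather than returning
#' `NaN`.
#'
#' @param bn an `mf_bn`.
#' @param nodes character vector of query node names (must not appear in
#'   the evidence).
#' @param evidence named list or character vector mapping observed nodes
#'   to states; may be empty.
#' @param order optional explicit elimination order (a permutation of the
#'   eliminable variables); by default min-fill.
#' @return For a single query node, a named probability vector over its
#'   states; for several, an array with one dimension per query node
#'   (dimnames are the state labels), in expand.grid order.
#' @export
bn_posterior <- function(bn, nodes, evidence = list(), order = NULL) {
  evidence <- as.list(evidence)
  if (length(intersect(nodes, names(evidence))))
    stop("query node(s) cannot also carry evidence")
  bad <- setdiff(c(nodes, names(evidence)), bn$dag$nodes)
  if (length(bad)) stop("unknown node(s): ", paste(bad, collapse = ", "))

  involved <- union(nodes, names(evidence))
  relevant <- union(involved, dag_ancestors(bn$dag, involved))
  factors <- lapply(bn$cpts[relevant], f_from_cpt)
  for (v in names(evidence))
    factors <- lapply(factors, f_reduce, var = v, state = evidence[[v]])

  elim <- setdiff(relevant, involved)
  if (is.null(order)) {
    order <- min_fill_order(lapply(factors, `[[`, "vars"), elim)
  } else {
    if (!all(elim %in% order))
      stop("elimination order must cover every eliminable variable")
    order <- order[order %in% elim]  # pruned or observed nodes drop out
  }
  for (v in order) {
    hit <- vapply(factors, function(f) v %in% f$vars, TRUE)
    if (!any(hit)) next
    newf <- f_sumout(f_product(factors[hit]), v)
    factors <- c(factors[!hit], list(newf))
  }
  res <- f_product(factors)
  total <- sum(res$val)
  if (!is.finite(total) || total <= 0)
    stop("impossible evidence: the observed states have probability 0 ",
         "under the model")
  val <- res$val / total
  # order result dimensions as the caller listed the query nodes
  dims <- vapply(res$states, length, 0L)
  arr <- array(val, dims, dimnames = res$states)
  if (length(res$vars) > 1) arr <- aperm(arr, match(nodes, res$vars))
  if (length(nodes) == 1L) {
    out <- as.vector(arr)
    names(out) <- bn$states[[nodes]]
    out
  } else arr
}

#' Marginal probability that a node is in its "present" state
#'
#' Thin wrapper over [bn_posterior()] returning, for each requested node,
#' the posterior probability of its last-listed state (`present` for
#' binary incident variables).
#'
#' @inheritParams bn_posterior
#' @return Named numeric vector of probabilities in `[0, 1]`.
#' @export
present_probability <- function(bn, nodes, evidence = list()) {
  vapply(nodes, function(v) {
    p <- bn_posterior(bn, v, evidence)
    unname(p[length(p)])
  }, 0)
}
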