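# Category-constrained greedy structure learning. The search is
# steepest-ascent hill climbing over add/delete/reverse edge moves with a
# per-record score-gain threshold for additions, a blacklist/whitelist,
# and category-ordering rules (attributional and system factors are
# roots; conditional factors precede knowledge/behavioral factors, which
# precede events; edges within the conditional and within the
# knowledge/behavioral ranks are allowed).

#' Category-ordering rules steering structure search
#'
#' @return List with `rank` (named integer category ranks), `no_parent`
#'   (categories whose nodes may not have parents) and `within`
#'   (categories allowing edges between two nodes of the same rank).
#' @export
default_category_rules <- function() {
  list(rank = c(attributional = 0L, system = 0L, conditional = 1L,
                knowledge_behavioral = 2L, event = 3L),
       no_parent = c("attributional", "system"),
       within = c("conditional", "knowledge_behavioral"))
}

#' Constraint set for structure search
#'
#' @param blacklist forbidden ordered edges: 2-column matrix/data.frame
#'   of (parent, child), or `NULL`.
#' @param whitelist forced ordered edges, same shape. The default is an
#'   empty whitelist, matching the published analysis.
#' @param category_rules see [default_category_rules()].
#' @return Object of class `mf_constraints`.
#' @export
constraint_set <- function(blacklist = NULL, whitelist = NULL,
                           category_rules = default_category_rules()) {
  norm <- function(x) {
    if (is.null(x) || NROW(x) == 0)
      return(matrix(character(0), ncol = 2,
                    dimnames = list(NULL, c("from", "to"))))
    x <- as.matrix(x)
    dimnames(x) <- list(NULL, c("from", "to"))
    storage.mode(x) <- "character"
    x[!duplicated(paste(x[, 1], x[, 2], sep = "\r")), , drop = FALSE]
  }
  bl <- norm(blacklist); wl <- norm(whitelist)
  if (nrow(bl) && nrow(wl)) {
    key <- function(m) paste(m[, 1], m[, 2], sep = "\r")
    if (length(intersect(key(bl), key(wl))))
      stop("an edge cannot be both blacklisted and whitelisted")
  }
  structure(list(blacklist = bl, whitelist = wl,
                 category_rules = category_rules),
            class = "mf_constraints")
}

#' @rdname constraint_set
#' @param codebook an `mf_codebook`; the default constraints carry the
#'   category rules only (empty blacklist and whitelist).
#' @export
default_constraints <- function(codebook = builtin_codebook()) {
  constraint_set()
}

# is parent -> child allowed by the category rules alone?
category_edge_ok <- function(parent_cat, child_cat, rules) {
  if (child_cat %in% rules$no_parent) return(FALSE)
  rp <- rules$rank[[parent_cat]]; rc <- rules$rank[[child_cat]]
  if (rp < rc) return(TRUE)
  rp == rc && child_cat %in% rules$within && parent_cat %in% rules$within
}

#' Structure-learning configuration
#'
#' @param score score family: `"aic"` (default), `"bic"` or `"loglik"`.
#'   All are smoothed log-likelihood scores; `aic`/`bic` subtract the
#'   usual complexity penalties.
#' @param threshold minimum per-record score gain (nats per record,
#'   default 0.02) required to accept an edge addition. Deletions and
#'   reversals only require strict total-score improvement.
#' @param max_parents cap on the parent-set size per node (default 3;
#'   small samples cannot support larger tables).
#' @param smoothing_alpha Laplace pseudo-count for CPT estimation
#'   (default 1).
#' @param seed integer seed used when `restarts > 1` to draw random
#'   starting graphs.
#' @param max_iterations cap on accepted moves per climb.
#' @param restarts number of hill-climbing restarts; the first always
#'   starts from the empty (plus whitelist) graph, further restarts from
#'   random legal graphs, and the best-scoring local optimum is kept.
#' @return Object of class `mf_learn_config`.
#' @export
learn_config <- function(score = c("aic", "bic", "loglik"), threshold = 0.02,
                         max_parents = 3L, smoothing_alpha = 1,
                         seed = 1L, max_iterations = 500L, restarts = 1L) {
  score <- match.arg(score)
  stopifnot(threshold >= 0, max_parents >= 1, smoothing_alpha > 0,
            max_iterations >= 1, restarts >= 1)
  structure(list(score = score, threshold = threshold,
                 max_parents = as.integer(max_parents),
                 smoothing_alpha = smoothing_alpha, seed = as.integer(seed),
                 max_iterations = as.integer(max_iterations),
                 restarts = as.integer(restarts)),
            class = "mf_learn_config")
}

# records -> integer state-code matrix in codebook node order
records_to_codes <- function(records, codebook) {
  records <- validate_records(records, codebook)
  states <- node_states(codebook)
  m <- vapply(node_names(codebook),
              function(v) match(records[[v]], states[[v]]),
              integer(nrow(records)))
  if (nrow(records) == 1L) m <- rbind(m)
  m
}

# decomposable local score of one family on the code matrix
score_family_codes <- function(M, nstates, child, parents, score, alpha) {
  n <- nrow(M)
  r <- nstates[[child]]
  idx <- M[, child]
  stride <- r
  for (p in parents) {
    idx <- idx + (M[, p] - 1L) * stride
    stride <- stride * nstates[[p]]
  }
  q <- as.integer(stride / r)
  counts <- matrix(tabulate(idx, nbins = stride), nrow = r)
  row_tot <- rep(colSums(counts), each = r)
  theta <- (counts + alpha) / (row_tot + alpha * r)
  ll <- sum(counts * log(theta))
  df <- (r - 1) * q
  switch(score,
         loglik = ll,
         aic = ll - df,
         bic = ll - 0.5 * log(n) * df)
}

#' Local (family) score of a node given a candidate parent set
#'
#' Smoothed log-likelihood of `node` given `parents`, minus the AIC or
#' BIC complexity penalty when selected. The score is decomposable:
#' greedy search accepts an edge addition when the resulting gain in this
#' score, divided by the number of records, reaches the configured
#' threshold. Higher is better.
#'
#' @param records validated record data.frame (at least one row).
#' @param node the child node name.
#' @param parents character vector of candidate parent names.
#' @param codebook an `mf_codebook`.
#' @param score `"aic"`, `"bic"` or `"loglik"`.
#' @param smoothing_alpha Laplace pseudo-count.
#' @return Total (not per-record) score, a scalar.
#' @export
score_family <- function(records, node, parents = character(),
                         codebook = builtin_codebook(),
                         score = "aic", smoothing_alpha = 1) {
  if (nrow(records) == 0) stop("cannot score an empty record set")
  M <- records_to_codes(records, codebook)
  nstates <- vapply(node_states(codebook), length, 0L)
  score_family_codes(M, nstates, node, parents, score, smoothing_alpha)
}

# transitive closure (reachability, excluding self) of adjacency matrix
reach_matrix <- function(adj) {
  reach <- adj
  repeat {
    nxt <- reach | ((reach %*% adj) > 0)
    if (identical(nxt, reach)) return(reach)
    reach <- nxt
  }
}

#' Greedy hill-climbing structure search
#'
#' Steepest-ascent hill climbing over edge additions, deletions and
#' reversals, under the constraint set: blacklisted edges are never
#' added, whitelisted edges are placed in the starting graph and never
#' removed, category rules restrict edge direction, and acyclicity and
#' the parent cap are enforced throughout. An addition is accepted only
#' if its per-record score gain reaches `config$threshold`; deletions and
#' reversals require strict total-score improvement. Ties between
#' equal-gain moves are broken by move type (add, delete, reverse) and
#' then lexicographically by (parent, child), so the search is
#' deterministic for a fixed input.
#'
#' @param records validated record data.frame.
#' @param codebook an `mf_codebook`.
#' @param constraints an `mf_constraints`.
#' @param config an `mf_learn_config`.
#' @param trace function called with one line of text per accepted move,
#'   e.g. `message`; `NULL` for silence.
#' @return An `mf_dag` at a local score optimum.
#' @export
greedy_search <- function(records, codebook = builtin_codebook(),
                          constraints = default_constraints(codebook),
                          config = learn_config(), trace = NULL) {
  M <- records_to_codes(records, codebook)
  n <- nrow(M)
  nodes <- node_names(codebook)
  p <- length(nodes)
  nstates <- vapply(node_states(codebook), length, 0L)
  cats <- node_categories(codebook)
  rules <- constraints$category_rules

  legal <- outer(seq_len(p), seq_len(p), Vectorize(function(i, j)
    i != j && category_edge_ok(cats[[i]], cats[[j]], rules)))
  dimnames(legal) <- list(nodes, nodes)
  if (nrow(constraints$blacklist))
    legal[constraints$blacklist] <- FALSE

  white <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  if (nrow(constraints$whitelist)) {
    wl <- constraints$whitelist
    if (any(!legal[wl]))
      stop("whitelisted edge(s) conflict with the blacklist or category rules")
    white[wl] <- TRUE
  }

  cache <- new.env(parent = emptyenv())
  local_score <- function(child, parents) {
    key <- paste0(child, "|", paste(sort(parents), collapse = ","))
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    val <- score_family_codes(M, nstates, child, parents,
                              config$score, config$smoothing_alpha)
    cache[[key]] <- val
    val
  }

  climb <- function(adj) {
    if (!igraph::is_dag(igraph::graph_from_adjacency_matrix(adj + 0)))
      stop("starting graph contains a cycle")
    pa_of <- function(v) nodes[adj[, v] > 0]
    for (it in seq_len(config$max_iterations)) {
      reach <- reach_matrix(adj)
      npar <- colSums(adj)
      best <- NULL  # list(delta, type_rank, from, to, apply)
      consider <- function(delta, type_rank, from, to, apply_fun, min_gain) {
        if (delta < min_gain) return()
        cand <- list(delta = delta, type = type_rank, from = from, to = to,
                     apply = apply_fun)
        if (is.null(best) ||
            delta > best$delta + 1e-12 ||
            (abs(delta - best$delta) <= 1e-12 &&
             (type_rank < best$type ||
              (type_rank == best$type &&
               (from < best$from || (from == best$from && to < best$to))))))
          best <<- cand
      }
      for (j in seq_len(p)) {
        to <- nodes[j]
        pa <- pa_of(to)
        s0 <- local_score(to, pa)
        for (i in seq_len(p)) {
          from <- nodes[i]
          if (adj[i, j]) {
            # delete (unless whitelisted)
            if (!white[i, j]) {
              d <- local_score(to, setdiff(pa, from)) - s0
              consider(d, 2L, from, to,
                       function(a, i., j.) { a[i., j.] <- 0L; a },
                       min_gain = 1e-9)
              # reverse: delete i->j, add j->i
              if (legal[j, i] && npar[i] < config$max_parents &&
                  !reach_without_edge(adj, reach, i, j)) {
                d2 <- d + local_score(from, c(pa_of(from), to)) -
                  local_score(from, pa_of(from))
                consider(d2, 3L, from, to,
                         function(a, i., j.) {
                           a[i., j.] <- 0L; a[j., i.] <- 1L; a
                         },
                         min_gain = 1e-9)
              }
            }
          } else if (legal[i, j] && !adj[j, i] && !reach[j, i] &&
                     npar[j] < config$max_parents) {
            d <- local_score(to, c(pa, from)) - s0
            consider(d, 1L, from, to,
                     function(a, i., j.) { a[i., j.] <- 1L; a },
                     min_gain = config$threshold * n)
          }
        }
      }
      if (is.null(best)) break
      adj <- best$apply(adj, match(best$from, nodes), match(best$to, nodes))
      if (!is.null(trace))
        trace(sprintf("move %d: %s %s -> %s (gain %.4f, %.5f/record)",
                      it, c("add", "delete", "reverse")[best$type],
                      best$from, best$to, best$delta, best$delta / n))
    }
    adj
  }

  start <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  start[white] <- 1L
  total_score <- function(adj) {
    sum(vapply(seq_len(p), function(j)
      local_score(nodes[j], nodes[adj[, j] > 0]), 0))
  }
  best_adj <- climb(start)
  if (config$restarts > 1) {
    best_sc <- total_score(best_adj)
    extra <- withr::with_seed(config$seed, lapply(seq_len(config$restarts - 1),
      function(k) random_legal_start(legal, white, config$max_parents)))
    for (st in extra) {
      a <- climb(st)
      sc <- total_score(a)
      if (sc > best_sc + 1e-9) { best_adj <- a; best_sc <- sc }
    }
  }
  idx <- which(best_adj > 0, arr.ind = TRUE)
  bn_dag(nodes, cbind(nodes[idx[, 1]], nodes[idx[, 2]]))
}

# does a path i ~> j persist after removing the direct edge i->j?
reach_without_edge <- function(adj, reach, i, j) {
  adj2 <- adj
  adj2[i, j] <- 0L
  r <- reach_matrix(adj2)
  r[i, j] > 0
}

random_legal_start <- function(legal, white, max_parents) {
  p <- nrow(legal)
  adj <- matrix(0L, p, p, dimnames = dimnames(legal))
  adj[white] <- 1L
  cand <- which(legal & !white & !t(white), arr.ind = TRUE)
  cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
  n_try <- min(nrow(cand), p)
  for (k in seq_len(n_try)) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (adj[j, i] || sum(adj[, j]) >= max_parents) next
    adj[i, j] <- 1L
    if (reach_matrix(adj)[j, i] > 0) adj[i, j] <- 0L
  }
  adj
}

#' Mechanized blacklist refinement
#'
#' The published analysis repeatedly re-ran the search, adding
#' causally-inconsistent edges to the blacklist until the model agreed
#' with the category ordering and time sequence of the factors. This
#' operation mechanizes one pass of that loop: every edge of `dag` that
#' violates the category rules (for example an event pointing at a
#' factor, or a knowledge/behavioral factor pointing at a conditional
#' factor) is appended to the blacklist. Iterating search and refinement
#' until the constraint set stops changing is the fixed point computed by
#' [learn_flow_model()].
#'
#' @param dag an `mf_dag` from [greedy_search()].
#' @param codebook an `mf_codebook`.
#' @param constraints the current `mf_constraints`.
#' @return An updated `mf_constraints` (identical when `dag` is already
#'   consistent).
#' @export
refine_blacklist <- function(dag, codebook = builtin_codebook(),
                             constraints = default_constraints(codebook)) {
  cats <- node_categories(codebook)
  rules <- constraints$category_rules
  e <- dag$edges
  if (!nrow(e)) return(constraints)
  bad <- !vapply(seq_len(nrow(e)), function(i)
    category_edge_ok(cats[[e[i, 1]]], cats[[e[i, 2]]], rules), TRUE)
  if (!any(bad)) return(constraints)
  constraint_set(blacklist = rbind(constraints$blacklist,
                                   e[bad, , drop = FALSE]),
                 whitelist = constraints$whitelist,
                 category_rules = rules)
}

#' Estimate CPTs from records with Laplace smoothing
#'
#' Each CPT cell is `(count + alpha) / (row_total + alpha * n_states)`,
#' so unseen parent configurations fall back to the uniform prior and
#' every scenario-analysis query stays defined on sparse data.
#'
#' @param records validated record data.frame.
#' @param dag an `mf_dag` over the codebook nodes.
#' @param codebook an `mf_codebook`.
#' @param smoothing_alpha Laplace pseudo-count (> 0).
#' @return An `mf_bn` carrying the codebook's categories and display
#'   labels.
#' @export
fit_cpts <- function(records, dag, codebook = builtin_codebook(),
                     smoothing_alpha = 1) {
  stopifnot(smoothing_alpha > 0)
  M <- records_to_codes(records, codebook)
  states <- node_states(codebook)
  nstates <- vapply(states, length, 0L)
  cpts <- lapply(dag$nodes, function(v) {
    pa <- dag_parents(dag, v)
    r <- nstates[[v]]
    idx <- M[, v]
    stride <- r
    for (p in pa) {
      idx <- idx + (M[, p] - 1L) * stride
      stride <- stride * nstates[[p]]
    }
    counts <- matrix(tabulate(idx, nbins = stride), nrow = r)
    row_tot <- rep(colSums(counts), each = r)
    prob <- (counts + smoothing_alpha) / (row_tot + smoothing_alpha * r)
    bn_cpt(v, states[[v]], t(prob), parents = pa,
           parent_states = states[pa])
  })
  discrete_bn(dag, cpts, categories = node_categories(codebook),
              display = display_names(codebook))
}

#' Learn a layered flow model from incident records
#'
#' The full published procedure: greedy constrained search, mechanized
#' blacklist refinement to a fixed point, CPT estimation with smoothing,
#' and longest-path layer assignment.
#'
#' @inheritParams greedy_search
#' @param max_refinements safety cap on search/refine iterations (the
#'   blacklist grows monotonically, so the loop always terminates within
#'   the number of possible edges).
#' @return Object of class `mf_flow_model`: list with `bn`, `layers`
#'   (see [assign_layers()]), `constraints` (final), `config`, and
#'   `n_refinements`.
#' @export
learn_flow_model <- function(records, codebook = builtin_codebook(),
                             constraints = default_constraints(codebook),
                             config = learn_config(), trace = NULL,
                             max_refinements = NULL) {
  p <- length(node_names(codebook))
  max_refinements <- max_refinements %||% (p * (p - 1L))
  n_ref <- 0L
  repeat {
    dag <- greedy_search(records, codebook, constraints, config, trace)
    updated <- refine_blacklist(dag, codebook, constraints)
    if (nrow(updated$blacklist) == nrow(constraints$blacklist)) break
    constraints <- updated
    n_ref <- n_ref + 1L
    if (!is.null(trace))
      trace(sprintf("blacklist refinement %d: now %d forbidden edges",
                    n_ref, nrow(constraints$blacklist)))
    if (n_ref >= max_refinements) break
  }
  bn <- fit_cpts(records, dag, codebook, config$smoothing_alpha)
  structure(list(bn = bn, layers = assign_layers(dag),
                 constraints = constraints, config = config,
                 n_refinements = n_ref),
            class = "mf_flow_model")
}

#' @export
print.mf_flow_model <- function(x, ...) {
  cat("Flow model:", nrow(x$bn$dag$edges), "edges,",
      x$layers$n_layers, "layers,",
      length(x$layers$excluded), "excluded node(s)\n")
  invisible(x)
}
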