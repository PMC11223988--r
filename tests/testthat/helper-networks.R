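# Shared fixture builders: small hand-set networks and random binary
# networks for oracle cross-checks.

# X -> Y with P(X=present)=0.5, P(Y=present|X)=0.1/0.9
two_node_bn <- function() {
  dag <- bn_dag(c("X", "Y"), rbind(c("X", "Y")))
  b <- c("absent", "present")
  discrete_bn(dag, list(
    bn_cpt("X", b, rbind(c(0.5, 0.5))),
    bn_cpt("Y", b, rbind(c(0.9, 0.1), c(0.1, 0.9)),
           parents = "X", parent_states = list(X = b))),
    categories = c(X = "knowledge_behavioral", Y = "event"))
}

# diamond: X1 -> X2, X1 -> X3, X2 -> Y, X3 -> Y, hand-set CPTs
diamond_bn <- function() {
  b <- c("absent", "present")
  dag <- bn_dag(c("X1", "X2", "X3", "Y"),
                rbind(c("X1", "X2"), c("X1", "X3"),
                      c("X2", "Y"), c("X3", "Y")))
  discrete_bn(dag, list(
    bn_cpt("X1", b, rbind(c(0.6, 0.4))),
    bn_cpt("X2", b, rbind(c(0.8, 0.2), c(0.3, 0.7)),
           parents = "X1", parent_states = list(X1 = b)),
    bn_cpt("X3", b, rbind(c(0.9, 0.1), c(0.4, 0.6)),
           parents = "X1", parent_states = list(X1 = b)),
    bn_cpt("Y", b, rbind(c(0.95, 0.05), c(0.5, 0.5),
                         c(0.6, 0.4), c(0.1, 0.9)),
           parents = c("X2", "X3"),
           parent_states = list(X2 = b, X3 = b))))
}

# random DAG over n binary nodes (ordered construction) with random CPTs
random_binary_bn <- function(n_nodes, seed, max_parents = 3,
                             edge_prob = 0.35) {
  withr::with_seed(seed, {
    nodes <- sprintf("V%02d", seq_len(n_nodes))
    b <- c("absent", "present")
    edges <- NULL
    for (j in seq_along(nodes)[-1]) {
      cand <- nodes[seq_len(j - 1)]
      pa <- cand[stats::runif(length(cand)) < edge_prob]
      if (length(pa) > max_parents) pa <- sample(pa, max_parents)
      if (length(pa)) edges <- rbind(edges, cbind(pa, nodes[j]))
    }
    dag <- bn_dag(nodes, edges)
    cpts <- lapply(nodes, function(v) {
      pa <- dag_parents(dag, v)
      q <- 2^length(pa)
      p1 <- stats::runif(q, 0.05, 0.95)
      bn_cpt(v, b, cbind(1 - p1, p1), parents = pa,
             parent_states = stats::setNames(rep(list(b), length(pa)), pa))
    })
    discrete_bn(dag, cpts)
  })
}

# posterior of `node` computed from the enumerated joint (brute force)
enum_posterior <- function(bn, node, evidence = list()) {
  ej <- bn_enumerate_joint(bn)
  keep <- rep(TRUE, nrow(ej))
  for (v in names(evidence)) keep <- keep & ej[[v]] == evidence[[v]]
  p <- vapply(bn$states[[node]], function(s)
    sum(ej$prob[keep & ej[[node]] == s]), 0)
  p / sum(p)
}

skeleton_key <- function(edges) {
  if (!NROW(edges)) return(character(0))
  paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]),
        sep = "~")
}

# records sampled from a ground-truth chain A -> B -> C (strong links)
chain_codebook <- function() codebook_from_nodes(c("A", "B", "C"))

chain_bn <- function() {
  b <- c("absent", "present")
  dag <- bn_dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  discrete_bn(dag, list(
    bn_cpt("A", b, rbind(c(0.5, 0.5))),
    bn_cpt("B", b, rbind(c(0.85, 0.15), c(0.25, 0.75)),
           parents = "A", parent_states = list(A = b)),
    bn_cpt("C", b, rbind(c(0.8, 0.2), c(0.2, 0.8)),
           parents = "B", parent_states = list(B = b))))
}
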