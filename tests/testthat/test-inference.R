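test_that("joint probability is the product of CPT factors", {
  bn <- two_node_bn()
  expect_equal(bn_joint_probability(bn, c(X = "present", Y = "present")),
               0.5 * 0.9)
  expect_equal(bn_joint_probability(bn, c(X = "absent", Y = "present")),
               0.5 * 0.1)

  # diamond topology: product of 4 hand-multiplied factors
  d <- diamond_bn()
  a <- c(X1 = "present", X2 = "absent", X3 = "present", Y = "absent")
  expect_equal(bn_joint_probability(d, a), 0.4 * 0.3 * 0.6 * 0.6)

  expect_error(bn_joint_probability(d, c(X1 = "present")), "missing")
  expect_error(bn_joint_probability(bn, c(X = "up", Y = "present")),
               "illegal state")
})

test_that("enumerated joint is exhaustive and normalized", {
  d <- diamond_bn()
  ej <- bn_enumerate_joint(d)
  expect_equal(nrow(ej), 16L)
  expect_equal(sum(ej$prob), 1, tolerance = 1e-12)

  bn3 <- random_binary_bn(3, seed = 2)
  expect_equal(nrow(bn_enumerate_joint(bn3)), 8L)

  # guard against state-space blowup
  big <- random_binary_bn(25, seed = 3, edge_prob = 0.05)
  expect_error(bn_enumerate_joint(big), "too large")
})

test_that("variable elimination agrees with enumeration and Bayes rule", {
  # single-node prior read-off
  b <- c("absent", "present")
  single <- discrete_bn(bn_dag("Z"), list(bn_cpt("Z", b, rbind(c(0.7, 0.3)))))
  expect_equal(unname(bn_posterior(single, "Z")), c(0.7, 0.3))

  # 2-node net, evidence on the child: Bayes rule by hand
  bn <- two_node_bn()
  # P(X=present | Y=present) = 0.5*0.9 / (0.5*0.9 + 0.5*0.1)
  expect_equal(bn_posterior(bn, "X", list(Y = "present"))[["present"]],
               0.9)

  # random nets: every query/evidence combination vs the oracle
  for (s in 1:20) {
    bn <- random_binary_bn(sample(4:8, 1), seed = 100 + s)
    nodes <- bn$dag$nodes
    q <- sample(nodes, 1)
    ev_nodes <- sample(setdiff(nodes, q), sample(0:2, 1))
    ev <- stats::setNames(as.list(sample(c("absent", "present"),
                                         length(ev_nodes), TRUE)), ev_nodes)
    expect_equal(unname(bn_posterior(bn, q, ev)),
                 unname(enum_posterior(bn, q, ev)),
                 tolerance = 1e-9, info = paste("net", s))
  }
})

test_that("posteriors are independent of the elimination order", {
  bn <- random_binary_bn(7, seed = 42)
  q <- "V07"
  ev <- list(V02 = "present")
  elim <- setdiff(bn$dag$nodes, c(q, names(ev)))
  ref <- bn_posterior(bn, q, ev)
  withr::with_seed(7, {
    for (k in 1:3) {
      ord <- sample(elim)
      expect_equal(bn_posterior(bn, q, ev, order = ord), ref,
                   tolerance = 1e-12)
    }
  })
})

test_that("impossible evidence raises an explicit error", {
  b <- c("absent", "present")
  dag <- bn_dag(c("X", "Y"), rbind(c("X", "Y")))
  bn <- discrete_bn(dag, list(
    bn_cpt("X", b, rbind(c(1, 0))),
    bn_cpt("Y", b, rbind(c(0.5, 0.5), c(0.5, 0.5)),
           parents = "X", parent_states = list(X = b))))
  expect_error(bn_posterior(bn, "Y", list(X = "present")),
               "impossible evidence")
})

test_that("CPT validation enforces shape and normalization", {
  b <- c("absent", "present")
  expect_error(bn_cpt("X", b, rbind(c(0.5, 0.6))), "sum to 1")
  expect_error(bn_cpt("X", b, rbind(c(1.2, -0.2))), "outside")
  expect_error(bn_cpt("Y", b, rbind(c(0.5, 0.5)),
                      parents = "X", parent_states = list(X = b)),
               "parent configurations")
  expect_error(
    discrete_bn(bn_dag(c("X", "Y"), rbind(c("X", "Y"))),
                list(bn_cpt("X", b, rbind(c(0.5, 0.5))),
                     bn_cpt("Y", b, rbind(c(0.5, 0.5))))),
    "do not match")
})

test_that("DAG validation rejects cycles, self-loops and stray nodes", {
  expect_error(bn_dag(c("A", "B"), rbind(c("A", "B"), c("B", "A"))),
               "cycle")
  expect_error(bn_dag("A", rbind(c("A", "A"))), "self-loop")
  expect_error(bn_dag("A", rbind(c("A", "B"))), "not declared")
  expect_error(bn_dag(c("A", "B"),
                      rbind(c("A", "B"), c("A", "B"))), "duplicate")
})

test_that("sampling is reproducible and consistent with exact marginals", {
  bn <- two_node_bn()
  s1 <- bn_sample(bn, 5, seed = 9)
  s2 <- bn_sample(bn, 5, seed = 9)
  expect_identical(s1, s2)

  # single node, prior 0.5: binomial 3-SD band at n = 10000
  b <- c("absent", "present")
  single <- discrete_bn(bn_dag("Z"), list(bn_cpt("Z", b, rbind(c(0.5, 0.5)))))
  s <- bn_sample(single, 10000, seed = 1)
  expect_lt(abs(mean(s$Z == "present") - 0.5), 3 * sqrt(0.25 / 10000))

  # every node of a random net: empirical vs exact marginal, 3-SD bands
  bn <- random_binary_bn(6, seed = 77)
  n <- 50000
  s <- bn_sample(bn, n, seed = 3)
  for (v in bn$dag$nodes) {
    p <- bn_posterior(bn, v)[["present"]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(s[[v]] == "present") - p), 3 * se + 1e-12)
  }
})

test_that("edge annotations equal conditional probabilities from the joint", {
  # single parent: direct CPT read-off
  bn <- two_node_bn()
  ep <- edge_probabilities(bn)
  expect_equal(ep$prob, 0.9)
  expect_equal(ep$from_state, "present")

  # two parents: against the enumeration oracle
  d <- diamond_bn()
  ep <- edge_probabilities(d)
  row <- ep[ep$from == "X2" & ep$to == "Y", ]
  expect_equal(row$prob,
               enum_posterior(d, "Y", list(X2 = "present"))[["present"]],
               tolerance = 1e-12)

  # multi-state parent: one value per non-reference state
  tri <- c("low", "mid", "high")
  b <- c("absent", "present")
  dag <- bn_dag(c("W", "E"), rbind(c("W", "E")))
  bn3 <- discrete_bn(dag, list(
    bn_cpt("W", tri, rbind(c(0.2, 0.3, 0.5))),
    bn_cpt("E", b, rbind(c(0.9, 0.1), c(0.7, 0.3), c(0.4, 0.6)),
           parents = "W", parent_states = list(W = tri))))
  ep3 <- edge_probabilities(bn3)
  expect_equal(nrow(ep3), 2L)
  expect_equal(ep3$from_state, c("mid", "high"))
  expect_equal(ep3$prob, c(0.3, 0.6))
})

test_that("network JSON serialization round-trips exactly", {
  for (bn in list(two_node_bn(), diamond_bn(), random_binary_bn(6, 5))) {
    path <- withr::local_tempfile(fileext = ".json")
    bn_to_json(bn, path)
    back <- bn_from_json(path)
    expect_equal(back$dag$edges, bn$dag$edges)
    expect_equal(back$states, bn$states)
    for (v in bn$dag$nodes) {
      expect_equal(back$cpts[[v]]$parents, bn$cpts[[v]]$parents)
      expect_equal(back$cpts[[v]]$prob, bn$cpts[[v]]$prob)
    }
  }
  # deterministic bytes
  expect_identical(bn_to_json(diamond_bn()), bn_to_json(diamond_bn()))
})

test_that("DOT export names every node and edge", {
  bn <- diamond_bn()
  dot <- bn_to_dot(bn)
  for (v in bn$dag$nodes) expect_match(dot, paste0('"', v, '"'))
  expect_match(dot, '"X2" -> "Y"')
  expect_match(dot, "label=")
})
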