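test_that("family scores separate dependence from independence", {
  cb <- chain_codebook()
  b <- c("absent", "present")

  # two independent coins: adding the parent gains < 0.02/record
  ind <- discrete_bn(bn_dag(c("A", "B")), list(
    bn_cpt("A", b, rbind(c(0.5, 0.5))),
    bn_cpt("B", b, rbind(c(0.6, 0.4)))))
  rec <- bn_sample(ind, 10000, seed = 21)
  rec$C <- rec$A  # C deterministically equals A
  n <- nrow(rec)
  gain_ind <- (score_family(rec, "B", "A", cb, score = "loglik") -
               score_family(rec, "B", character(0), cb, score = "loglik")) / n
  expect_lt(gain_ind, 0.02)
  expect_gt(gain_ind, -0.001)

  # deterministic copy: per-record gain equals the marginal entropy
  gain_det <- (score_family(rec, "C", "A", cb, score = "loglik") -
               score_family(rec, "C", character(0), cb, score = "loglik")) / n
  p <- mean(rec$C == "present")
  entropy <- -p * log(p) - (1 - p) * log(1 - p)
  expect_gt(gain_det, 0.02)
  expect_equal(gain_det, entropy, tolerance = 0.01)

  # huge smoothing pulls the score towards the uniform model
  sc_big_alpha <- score_family(rec[1:50, ], "A", character(0), cb,
                               score = "loglik", smoothing_alpha = 1e7)
  expect_equal(sc_big_alpha, 50 * log(0.5), tolerance = 1e-3)

  expect_error(score_family(rec[0, ], "A", character(0), cb), "empty")
})

test_that("greedy search recovers a strong chain at n = 5000", {
  cb <- chain_codebook()
  rec <- bn_sample(chain_bn(), 5000, seed = 31)
  dag <- greedy_search(rec, cb, config = learn_config())
  expect_equal(sort(skeleton_key(dag$edges)),
               sort(skeleton_key(rbind(c("A", "B"), c("B", "C")))))
})

test_that("constraints are honoured by construction", {
  cb <- chain_codebook()
  rec <- bn_sample(chain_bn(), 2000, seed = 32)
  all_pairs <- expand.grid(from = c("A", "B", "C"), to = c("A", "B", "C"),
                           stringsAsFactors = FALSE)
  all_pairs <- all_pairs[all_pairs$from != all_pairs$to, ]

  # forbidding every edge forces the empty graph
  dag <- greedy_search(rec, cb,
                       constraint_set(blacklist = as.matrix(all_pairs)),
                       learn_config())
  expect_equal(nrow(dag$edges), 0L)

  # a whitelisted edge is always present, even a useless one
  dag <- greedy_search(rec, cb,
                       constraint_set(whitelist = rbind(c("C", "A"))),
                       learn_config())
  expect_true(any(dag$edges[, 1] == "C" & dag$edges[, 2] == "A"))

  # blacklisted edge never appears
  dag <- greedy_search(rec, cb,
                       constraint_set(blacklist = rbind(c("A", "B"),
                                                        c("B", "A"))),
                       learn_config())
  expect_false(any(skeleton_key(dag$edges) == skeleton_key(rbind(c("A", "B")))))

  expect_error(constraint_set(blacklist = rbind(c("A", "B")),
                              whitelist = rbind(c("A", "B"))),
               "both")
})

test_that("category rules block events from parenting factors", {
  rules <- default_category_rules()
  cb <- builtin_codebook()
  cats <- node_categories(cb)
  gen <- generate_dataset(truth_spec(cb, n = 1000, seed = 41))
  dag <- greedy_search(gen$records, cb, config = learn_config())
  rank <- rules$rank
  for (i in seq_len(nrow(dag$edges))) {
    pc <- cats[[dag$edges[i, 1]]]
    cc <- cats[[dag$edges[i, 2]]]
    expect_false(cc %in% rules$no_parent)
    expect_lte(rank[[pc]], rank[[cc]])
  }
})

test_that("raising the threshold never increases the edge count", {
  cb <- chain_codebook()
  rec <- bn_sample(chain_bn(), 3000, seed = 51)
  counts <- vapply(c(0, 0.01, 0.05, 0.2, 0.7), function(thr)
    nrow(greedy_search(rec, cb,
                       config = learn_config(threshold = thr))$edges), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("search is deterministic for identical inputs", {
  cb <- builtin_codebook()
  gen <- generate_dataset(truth_spec(cb, n = 800, seed = 61))
  d1 <- greedy_search(gen$records, cb, config = learn_config())
  d2 <- greedy_search(gen$records, cb, config = learn_config())
  expect_identical(d1$edges, d2$edges)
})

test_that("six-node ground truth is recovered near-perfectly", {
  # strong dependencies (contrasts >= 0.3): mean SHD over 20 seeds <= 1
  b <- c("absent", "present")
  cbs <- codebook_from_nodes(sprintf("N%d", 1:6))
  dag <- bn_dag(sprintf("N%d", 1:6),
                rbind(c("N1", "N3"), c("N2", "N3"), c("N3", "N4"),
                      c("N3", "N5"), c("N4", "N6")))
  mk <- function(v, pa, rows) bn_cpt(v, b, rows, parents = pa,
    parent_states = stats::setNames(rep(list(b), length(pa)), pa))
  truth <- discrete_bn(dag, list(
    mk("N1", character(0), rbind(c(0.55, 0.45))),
    mk("N2", character(0), rbind(c(0.4, 0.6))),
    mk("N3", c("N1", "N2"), rbind(c(0.9, 0.1), c(0.55, 0.45),
                                  c(0.5, 0.5), c(0.15, 0.85))),
    mk("N4", "N3", rbind(c(0.75, 0.25), c(0.3, 0.7))),
    mk("N5", "N3", rbind(c(0.85, 0.15), c(0.45, 0.55))),
    mk("N6", "N4", rbind(c(0.7, 0.3), c(0.25, 0.75)))))
  shd <- vapply(1:20, function(s) {
    rec <- bn_sample(truth, 5000, seed = 700 + s)
    est <- greedy_search(rec, cbs, config = learn_config())
    true_k <- skeleton_key(dag$edges)
    est_k <- skeleton_key(est$edges)
    length(setdiff(true_k, est_k)) + length(setdiff(est_k, true_k))
  }, 0)
  expect_lte(mean(shd), 1)
})

test_that("blacklist refinement flags category-violating edges", {
  cb <- builtin_codebook()
  cons <- default_constraints(cb)
  dag_bad <- bn_dag(node_names(cb),
                    rbind(c("wrong_dose", "time_pressure"),
                          c("time_pressure", "failure_to_confirm_5_rights")))
  upd <- refine_blacklist(dag_bad, cb, cons)
  expect_equal(nrow(upd$blacklist), 1L)
  expect_equal(unname(upd$blacklist[1, ]),
               c("wrong_dose", "time_pressure"))

  # consistent DAG: fixed point
  dag_ok <- bn_dag(node_names(cb),
                   rbind(c("time_pressure", "failure_to_confirm_5_rights")))
  expect_identical(refine_blacklist(dag_ok, cb, cons), cons)
})

test_that("CPT estimation applies Laplace smoothing correctly", {
  cb <- chain_codebook()
  # hand-built records: B has counts (9 absent, 1 present)
  rec <- data.frame(A = rep("present", 10),
                    B = c(rep("absent", 9), "present"),
                    C = rep("absent", 10), stringsAsFactors = FALSE)
  dag <- bn_dag(c("A", "B", "C"))
  bn <- fit_cpts(rec, dag, cb, smoothing_alpha = 1)
  expect_equal(unname(bn$cpts$B$prob[1, ]), c(10 / 12, 2 / 12))

  # unseen parent configuration falls back to the uniform prior
  dag2 <- bn_dag(c("A", "B", "C"), rbind(c("A", "B")))
  bn2 <- fit_cpts(rec, dag2, cb, smoothing_alpha = 1)
  expect_equal(unname(bn2$cpts$B$prob[1, ]), c(0.5, 0.5))  # A=absent unseen

  # root-node frequencies, small alpha: published-style read-off
  cb34 <- builtin_codebook()
  rr <- reference_records(cb34)
  bn3 <- fit_cpts(rr, bn_dag(node_names(cb34)), cb34,
                  smoothing_alpha = 1e-9)
  expect_equal(unname(bn3$cpts$wrong_dose$prob[1, "present"]), 43 / 119,
               tolerance = 1e-6)
  expect_equal(unname(round(100 * bn3$cpts$wrong_dose$prob[1, "present"], 1)),
               36.1)
})

test_that("layer assignment follows longest paths and drops isolates", {
  chain <- bn_dag(sprintf("L%d", 1:5),
                  cbind(sprintf("L%d", 1:4), sprintf("L%d", 2:5)))
  lay <- assign_layers(chain)
  expect_equal(lay$n_layers, 5L)
  expect_equal(unname(lay$layers[sprintf("L%d", 1:5)]), 1:5)

  iso <- bn_dag(c("A", "B", "C"), rbind(c("A", "B")))
  lay <- assign_layers(iso)
  expect_equal(lay$excluded, "C")
  expect_false("C" %in% names(lay$layers))

  # every edge spans strictly increasing layers on a random DAG
  bn <- random_binary_bn(8, seed = 91)
  lay <- assign_layers(bn$dag)
  for (i in seq_len(nrow(bn$dag$edges))) {
    e <- bn$dag$edges[i, ]
    expect_lt(lay$layers[[e[1]]], lay$layers[[e[2]]])
  }
})

test_that("the search/refine loop reaches a consistent fixed point", {
  cb <- builtin_codebook()
  gen <- generate_dataset(truth_spec(cb, n = 600, seed = 71))
  model <- learn_flow_model(gen$records, cb, config = learn_config())
  expect_s3_class(model$bn, "mf_bn")
  # final model violates no category rule (so refinement has converged)
  expect_identical(refine_blacklist(model$bn$dag, cb, model$constraints),
                   model$constraints)
  # layers: every edge increases strictly
  for (i in seq_len(nrow(model$bn$dag$edges))) {
    e <- model$bn$dag$edges[i, ]
    expect_lt(model$layers$layers[[e[1]]], model$layers$layers[[e[2]]])
  }
})

test_that("constraint files round-trip through JSON and YAML", {
  cons <- constraint_set(
    blacklist = rbind(c("wrong_dose", "time_pressure")),
    whitelist = rbind(c("time_pressure", "task_interruption")))
  js <- withr::local_tempfile(fileext = ".json")
  write_constraints(cons, js)
  back <- read_constraints(js)
  expect_equal(back$blacklist, cons$blacklist)
  expect_equal(back$whitelist, cons$whitelist)

  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("blacklist:",
               "  - [wrong_dose, time_pressure]",
               "whitelist: []"), yml)
  y <- read_constraints(yml)
  expect_equal(unname(y$blacklist[1, ]), c("wrong_dose", "time_pressure"))
  expect_equal(nrow(y$whitelist), 0L)
})
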