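# Synthetic incident-report generator. A known ground-truth layered
# network over the codebook is built (category ordering respected), its
# CPTs are calibrated so that every node's exact marginal matches the
# published frequency table, and records are drawn by ancestral sampling
# with rejection of reports that document no event — mirroring that the
# source database contains only incident reports.

#' Default ground-truth DAG over the codebook
#'
#' Builds a plausible layered causal emulation for testing: attributional
#' and system factors are roots; binary conditional factors receive 0-2
#' root parents (work time and patient age stay exogenous context
#' variables); knowledge/behavioral factors receive 1-2 conditional
#' parents; each event receives 1-3 knowledge/behavioral parents. Parent
#' choices are random but weighted by the candidate parent's marginal
#' variability (a near-degenerate factor carries little signal and, as in
#' the published model, tends to stay peripheral). A fixed backbone chain
#' — tenure in the current setting, time pressure, assumptions and
#' forgetfulness, failure to confirm the 5 rights, wrong dose — plus one
#' knowledge-to-behavior edge (insufficient knowledge of medications
#' driving improper handling) guarantees a 5-layer model, the depth the
#' published flow model reports. Deterministic for a fixed seed.
#'
#' @param codebook an `mf_codebook`.
#' @param seed integer seed.
#' @return An `mf_dag` obeying the default category ordering.
#' @export
default_truth_dag <- function(codebook = builtin_codebook(), seed = 1L) {
  cats <- node_categories(codebook)
  marg <- codebook_marginals(codebook)
  nm <- node_names(codebook)
  roots <- nm[cats %in% c("attributional", "system")]
  conditional <- nm[cats == "conditional"]
  kb <- nm[cats == "knowledge_behavioral"]
  events <- nm[cats == "event"]
  exogenous <- c("work_time", "patient_age")

  # selection weight: Gini-style variability of the marginal
  wt <- vapply(marg, function(p) (1 - sum(p^2)) / 2, 0)

  backbone <- rbind(
    c("years_current_work_setting", "time_pressure"),
    c("time_pressure", "assumptions_and_forgetfulness"),
    c("assumptions_and_forgetfulness", "failure_to_confirm_5_rights"),
    c("failure_to_confirm_5_rights", "wrong_dose"),
    c("insufficient_knowledge_of_medications",
      "improper_handling_of_medications"))

  withr::with_seed(seed, {
    edges <- backbone
    forced_parents <- function(child)
      edges[edges[, 2] == child, 1]
    pick <- function(pool, k) {
      pool <- setdiff(pool, character(0))
      if (k <= 0 || !length(pool)) return(character(0))
      k <- min(k, length(pool))
      if (length(pool) == 1) return(pool)
      sample(pool, k, prob = wt[pool])
    }
    add <- function(child, pool, k) {
      extra <- pick(setdiff(pool, forced_parents(child)), k)
      for (pa in extra) edges <<- rbind(edges, c(pa, child))
    }
    for (v in setdiff(conditional, exogenous)) {
      n_have <- length(forced_parents(v))
      n_want <- sample(0:2, 1, prob = c(0.3, 0.5, 0.2))
      add(v, roots, n_want - n_have)
    }
    for (v in kb) {
      n_have <- length(forced_parents(v))
      n_want <- sample(1:2, 1, prob = c(0.6, 0.4))
      add(v, conditional, n_want - n_have)
    }
    for (v in events) {
      n_have <- length(forced_parents(v))
      n_want <- sample(1:3, 1, prob = c(0.4, 0.4, 0.2))
      add(v, kb, n_want - n_have)
    }
  })
  bn_dag(nm, edges)
}

# graded parent weight: absent/first state 0, last state 1
parent_weights <- function(states) {
  lapply(states, function(s) seq(0, 1, length.out = length(s)))
}

#' Calibrate ground-truth CPTs to target marginals
#'
#' Topological-order calibration. Roots take their target marginal as
#' the prior. For a binary child, the probability of `present` under a
#' parent configuration is `min(leak + effect_size * sum(w), 0.99)`,
#' where `w` are graded parent weights (0 for the first state, 1 for the
#' last, linear in between): an additive risk-difference model under
#' which each contributing factor independently adds the full effect
#' size to the child's risk, so every edge carries the same contrast
#' regardless of how many co-parents the child has. The baseline `leak`
#' is solved by bisection so that the child's exact marginal (by
#' variable elimination over the already-calibrated ancestors) matches
#' the target within 1e-4, with `leak` clipped to `[0.01, 0.99]`; when
#' the clip binds (targets rarer than the effect size allows), the
#' contrast is preserved and the residual marginal error is reported
#' rather than silently absorbed. Multi-state nodes are supported as
#' roots only (the default truth keeps them exogenous).
#'
#' @param dag an `mf_dag`.
#' @param targets named list of per-state target marginals (see
#'   [codebook_marginals()]), or for binary nodes a single `present`
#'   probability.
#' @param effect_size CPT contrast between all-present and all-absent
#'   parent configurations (default 0.3).
#' @param codebook an `mf_codebook` supplying states and metadata.
#' @return List with `bn` (an `mf_bn`) and `report` (data.frame: `node`,
#'   `target`, `achieved`, `abs_error`, `clipped`).
#' @export
calibrate_cpts <- function(dag, targets = codebook_marginals(codebook),
                           effect_size = 0.3,
                           codebook = builtin_codebook()) {
  states <- node_states(codebook)
  topo <- dag_topo_sort(dag)
  cpts <- list()
  report <- list()
  partial_bn <- NULL
  done <- character(0)
  for (v in topo) {
    pa <- dag_parents(dag, v)
    tv <- targets[[v]]
    if (is.null(tv)) stop("no target marginal for node '", v, "'")
    if (length(tv) == 1 && length(states[[v]]) == 2)
      tv <- c(1 - tv, tv)
    if (!length(pa)) {
      cpts[[v]] <- bn_cpt(v, states[[v]], rbind(tv / sum(tv)))
      report[[v]] <- data.frame(node = v, target = tv[length(tv)],
                                achieved = tv[length(tv)], abs_error = 0,
                                clipped = FALSE)
    } else {
      if (length(states[[v]]) != 2)
        stop("calibration supports multi-state nodes as roots only ('",
             v, "' has parents)")
      target <- unname(tv[length(tv)])  # probability of the last state
      # joint distribution of the parent configuration, from the
      # already-calibrated ancestor sub-network
      sub_bn <- discrete_bn(bn_dag(done, keep_edges(dag, done)),
                            cpts[done])
      pj <- bn_posterior(sub_bn, pa)
      grid <- expand.grid(states[pa], stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
      pw <- parent_weights(states[pa])
      wsum <- Reduce(`+`, lapply(seq_along(pa), function(j)
        pw[[j]][match(grid[[j]], states[[pa[j]]])]))
      pcfg <- as.vector(pj)  # expand.grid order, first parent fastest
      # additive risk difference: each fully-present parent adds
      # effect_size to the child risk; only the baseline moves, clipped
      # so every entry stays inside [0.01, 0.99]
      lo <- 0.01; hi <- 0.99
      marg_at <- function(leak)
        sum(pcfg * pmin(leak + effect_size * wsum, 0.99))
      clipped <- FALSE
      if (marg_at(lo) >= target) { leak <- lo; clipped <- TRUE }
      else if (marg_at(hi) <= target) { leak <- hi; clipped <- TRUE }
      else for (k in 1:60) {
        mid <- (lo + hi) / 2
        if (marg_at(mid) < target) lo <- mid else hi <- mid
        leak <- (lo + hi) / 2
      }
      p_present <- pmin(leak + effect_size * wsum, 0.99)
      achieved <- sum(pcfg * p_present)
      cpts[[v]] <- bn_cpt(v, states[[v]],
                          cbind(1 - p_present, p_present),
                          parents = pa, parent_states = states[pa])
      report[[v]] <- data.frame(node = v, target = target,
                                achieved = achieved,
                                abs_error = abs(achieved - target),
                                clipped = clipped)
    }
    done <- c(done, v)
  }
  report <- do.call(rbind, report[node_names(codebook)])
  rownames(report) <- NULL
  bn <- discrete_bn(dag, cpts[dag$nodes],
                    categories = node_categories(codebook),
                    display = display_names(codebook))
  list(bn = bn, report = report)
}

keep_edges <- function(dag, nodes) {
  e <- dag$edges
  e[e[, 1] %in% nodes & e[, 2] %in% nodes, , drop = FALSE]
}

#' Ground-truth specification for synthetic data
#'
#' @param codebook an `mf_codebook`.
#' @param dag ground-truth DAG; default [default_truth_dag()] under
#'   `seed`.
#' @param effect_size CPT contrast (default 0.3): strong enough for
#'   structure recovery at simulation scale, weak enough to be realistic
#'   for behavioral risk factors.
#' @param target_marginals named list of per-state marginal targets;
#'   default the published frequency distribution
#'   ([codebook_marginals()]).
#' @param n number of records (default 119, the published sample size).
#' @param seed integer seed controlling the DAG draw and the sampling.
#' @return Object of class `mf_truth_spec`.
#' @export
truth_spec <- function(codebook = builtin_codebook(), dag = NULL,
                       effect_size = 0.3, target_marginals = NULL,
                       n = 119L, seed = 1L) {
  stopifnot(n >= 1, effect_size >= 0)
  structure(list(codebook = codebook,
                 dag = dag %||% default_truth_dag(codebook, seed),
                 effect_size = effect_size,
                 target_marginals = target_marginals %||%
                   codebook_marginals(codebook),
                 n = as.integer(n), seed = as.integer(seed)),
            class = "mf_truth_spec")
}

#' Generate a synthetic incident-report dataset
#'
#' Calibrates the ground-truth CPTs ([calibrate_cpts()]), then draws
#' records by ancestral sampling, rejecting draws in which no event is
#' `present` (the source database contains only reports that document an
#' incident). Marginal targets are interpreted pre-rejection; the
#' conditioning introduces a documented upward bias on event-ancestor
#' marginals. Reproducible for a fixed seed.
#'
#' @param spec an `mf_truth_spec`.
#' @return List with `records` (validated data.frame of `spec$n` rows),
#'   `bn` (the ground-truth `mf_bn`), `report` (calibration report) and
#'   `acceptance_rate` (fraction of raw draws that documented an event).
#' @export
generate_dataset <- function(spec = truth_spec()) {
  cal <- calibrate_cpts(spec$dag, spec$target_marginals, spec$effect_size,
                        spec$codebook)
  events <- node_names(spec$codebook)[
    node_categories(spec$codebook) == "event"]
  n <- spec$n
  kept <- NULL
  drawn <- 0L
  batch_seed <- spec$seed
  while (is.null(kept) || nrow(kept) < n) {
    batch <- max(2L * n, 512L)
    smp <- bn_sample(cal$bn, batch, seed = batch_seed)
    batch_seed <- batch_seed + 1000003L
    drawn <- drawn + batch
    any_ev <- Reduce(`|`, lapply(events, function(v) smp[[v]] == "present"))
    kept <- rbind(kept, smp[any_ev, , drop = FALSE])
    if (drawn >= 100L * n && nrow(kept) / drawn < 0.01)
      stop("rejection rate above 99%: marginal targets make an eventful ",
           "report too rare; raise the event targets or the effect size")
  }
  records <- kept[seq_len(n), , drop = FALSE]
  rownames(records) <- NULL
  list(records = validate_records(records, spec$codebook),
       bn = cal$bn, report = cal$report,
       acceptance_rate = nrow(kept) / drawn)
}
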