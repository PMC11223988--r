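# Scenario analysis: suppress individual factors (force their prior
# probability of being present to 0) and recompute posterior event
# probabilities. Two well-defined readings of "set the prior to 0%" are
# provided: a do-intervention (graph surgery: incoming edges of the
# controlled node are removed and the node is clamped) and plain
# evidence conditioning. The intervention reading is the default, since
# the quantity of interest is the effect of eliminating a factor through
# education — a manipulation, not an observation.

event_nodes_of <- function(bn) {
  if (is.null(bn$categories)) stop("network carries no category metadata; ",
                                   "pass `events` explicitly")
  names(bn$categories)[bn$categories == "event"]
}

kb_nodes_of <- function(bn) {
  if (is.null(bn$categories)) stop("network carries no category metadata; ",
                                   "pass `factors` explicitly")
  names(bn$categories)[bn$categories == "knowledge_behavioral"]
}

#' Base (uncontrolled) event probabilities
#'
#' Exact marginal probability that each event is `present`, as a
#' percentage — the "Base" column of the scenario report.
#'
#' @param bn an `mf_bn`.
#' @param events event node names; defaults to the network's event-
#'   category nodes.
#' @return Named numeric vector of percentages in `[0, 100]`.
#' @export
base_event_probabilities <- function(bn, events = NULL) {
  events <- events %||% event_nodes_of(bn)
  100 * present_probability(bn, events)
}

#' Build the controlled inference problem for a scenario
#'
#' @param bn an `mf_bn`.
#' @param controlled named character vector mapping controlled factor
#'   nodes to their forced state, or a bare character vector of node
#'   names (forced to `"absent"`).
#' @param mode `"do"` (graph surgery: remove incoming edges and clamp the
#'   node — intervention semantics) or `"condition"` (treat the forced
#'   state as observed evidence; no surgery).
#' @return Object of class `mf_control`: list with `bn` (mutilated under
#'   `"do"`, untouched under `"condition"`), `evidence` (non-empty only
#'   under `"condition"`) and `mode`.
#' @export
apply_control <- function(bn, controlled, mode = c("do", "condition")) {
  mode <- match.arg(mode)
  if (is.null(names(controlled)))
    controlled <- stats::setNames(rep("absent", length(controlled)),
                                  controlled)
  controlled <- unlist(controlled)
  bad <- setdiff(names(controlled), bn$dag$nodes)
  if (length(bad)) stop("unknown node(s): ", paste(bad, collapse = ", "))
  for (v in names(controlled))
    if (!(controlled[[v]] %in% bn$states[[v]]))
      stop(sprintf("illegal forced state '%s' for node '%s'",
                   controlled[[v]], v))
  if (mode == "condition")
    return(structure(list(bn = bn, evidence = as.list(controlled),
                          mode = mode), class = "mf_control"))
  # graph surgery
  dag <- bn$dag
  keep <- !(dag$edges[, 2] %in% names(controlled))
  dag <- bn_dag(dag$nodes, dag$edges[keep, , drop = FALSE])
  cpts <- bn$cpts
  for (v in names(controlled)) {
    point <- as.numeric(bn$states[[v]] == controlled[[v]])
    cpts[[v]] <- bn_cpt(v, bn$states[[v]], rbind(point))
  }
  structure(list(bn = discrete_bn(dag, cpts, categories = bn$categories,
                                  display = bn$display),
                 evidence = list(), mode = mode),
            class = "mf_control")
}

#' Posterior event probability under a control
#'
#' @param control an `mf_control` from [apply_control()].
#' @param events event node names.
#' @return Named numeric vector of percentages.
#' @export
controlled_event_probabilities <- function(control, events) {
  100 * present_probability(control$bn, events, evidence = control$evidence)
}

#' Run the factor-suppression scenario analysis
#'
#' For each factor in turn, forces the factor to `absent` (prior
#' probability of being present 0%) and recomputes the exact posterior
#' probability of every event. Mirroring the published report, a cell is
#' produced only for (event, factor) pairs where the factor is an
#' ancestor of the event in the network (other pairs are unaffected by
#' construction under intervention semantics); `full_grid = TRUE` forces
#' every pair.
#'
#' @param bn an `mf_bn`.
#' @param events event node names (default: the network's event nodes).
#' @param factors factor nodes to suppress one at a time (default: the
#'   network's knowledge/behavioral nodes).
#' @param mode `"do"` (default) or `"condition"`, see [apply_control()].
#' @param full_grid report every (event, factor) pair, connected or not.
#' @return Object of class `mf_scenario_result`: data.frame with columns
#'   `event`, `factor`, `base_pct`, `posterior_pct`, `abs_reduction`,
#'   `rel_reduction`; the control mode is kept in attribute `mode`.
#' @export
run_scenarios <- function(bn, events = NULL, factors = NULL,
                          mode = c("do", "condition"), full_grid = FALSE) {
  mode <- match.arg(mode)
  events <- events %||% event_nodes_of(bn)
  factors <- factors %||% kb_nodes_of(bn)
  if (length(intersect(events, factors)))
    stop("controlled factors must not be event nodes")
  base <- base_event_probabilities(bn, events)
  rows <- list()
  for (f in factors) {
    desc_events <- if (full_grid) events else
      intersect(events, descendants_of(bn$dag, f))
    if (!length(desc_events)) next
    ctrl <- apply_control(bn, f, mode = mode)
    post <- controlled_event_probabilities(ctrl, desc_events)
    rows[[f]] <- data.frame(event = desc_events, factor = f,
                            base_pct = unname(base[desc_events]),
                            posterior_pct = unname(post),
                            stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(event = character(0), factor = character(0),
               base_pct = numeric(0), posterior_pct = numeric(0))
  rownames(out) <- NULL
  out$abs_reduction <- out$base_pct - out$posterior_pct
  out$rel_reduction <- ifelse(out$base_pct > 0,
                              out$abs_reduction / out$base_pct, 0)
  # order rows: events by descending base probability, then factor name
  ev_order <- names(sort(base, decreasing = TRUE))
  out <- out[order(match(out$event, ev_order), out$factor), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, mode = mode, base = base,
            class = c("mf_scenario_result", "data.frame"))
}

descendants_of <- function(dag, node) {
  g <- as_igraph(dag)
  setdiff(names(igraph::subcomponent(g, node, mode = "out")), node)
}

#' Rank factors by total absolute risk reduction
#'
#' Sums `base - posterior` (percentage points) over all reported events
#' for each factor and ranks factors by the total, descending; ties are
#' broken by factor name.
#'
#' @param result an `mf_scenario_result`.
#' @return data.frame with columns `factor`, `total_abs_reduction`,
#'   `n_events`, ordered by decreasing total reduction.
#' @export
rank_factors <- function(result) {
  if (!nrow(result))
    return(data.frame(factor = character(0),
                      total_abs_reduction = numeric(0),
                      n_events = integer(0)))
  agg <- stats::aggregate(abs_reduction ~ factor, data = result, FUN = sum)
  cnt <- stats::aggregate(event ~ factor, data = result, FUN = length)
  out <- merge(agg, cnt, by = "factor")
  names(out) <- c("factor", "total_abs_reduction", "n_events")
  out <- out[order(-out$total_abs_reduction, out$factor), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a scenario report in the published table's layout
#'
#' One block per event (base probability on the event row) with one
#' sub-row per controlled factor carrying the posterior probability;
#' percentages to one decimal. The control mode is recorded in the
#' output (a `mode` column in CSV; the header line in Markdown).
#'
#' @param result an `mf_scenario_result`.
#' @param path file to write.
#' @param format `"csv"` or `"md"`; inferred from the extension when
#'   `NULL`.
#' @return `path`, invisibly.
#' @export
write_scenario_report <- function(result, path, format = NULL) {
  format <- format %||% tolower(tools::file_ext(path))
  mode <- attr(result, "mode") %||% "do"
  events <- unique(result$event)
  if (format == "csv") {
    rows <- list()
    for (ev in events) {
      sub <- result[result$event == ev, , drop = FALSE]
      rows[[length(rows) + 1]] <- data.frame(
        row = ev, posterior_pct = NA_real_,
        base_pct = round(sub$base_pct[1], 1), mode = mode)
      for (i in seq_len(nrow(sub)))
        rows[[length(rows) + 1]] <- data.frame(
          row = sub$factor[i],
          posterior_pct = round(sub$posterior_pct[i], 1),
          base_pct = NA_real_, mode = mode)
    }
    utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                     na = "")
  } else if (format == "md") {
    lines <- c(sprintf("# Event probability under factor suppression (mode: %s)",
                       mode), "",
               "| Event / controlled factor | Posterior (%) | Base (%) |",
               "|---|---|---|")
    for (ev in events) {
      sub <- result[result$event == ev, , drop = FALSE]
      lines <- c(lines, sprintf("| **%s** |  | %.1f |", ev, sub$base_pct[1]))
      for (i in seq_len(nrow(sub)))
        lines <- c(lines, sprintf("| %s | %.1f |  |",
                                  sub$factor[i], sub$posterior_pct[i]))
    }
    writeLines(lines, path)
  } else stop("unsupported report format: ", format)
  invisible(path)
}
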