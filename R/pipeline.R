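# End-to-end pipeline stages (describe / learn / scenario / synth) with
# file outputs and a reproducibility manifest. These functions are the
# command surface: the shipped CLI script (inst/cli/medflow.R) is a thin
# argument-parsing wrapper over them, so library calls and shell runs
# produce identical bytes.

ensure_dir <- function(path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  path
}

as_records <- function(input, codebook) {
  if (is.data.frame(input)) validate_records(input, codebook)
  else read_records(input, codebook)
}

write_manifest <- function(out_dir, stage, params, inputs = character(0)) {
  manifest <- list(
    stage = stage,
    package = "medflow",
    version = as.character(utils::packageVersion("medflow")),
    params = params,
    input_md5 = as.list(tools::md5sum(inputs))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Descriptive-statistics stage
#'
#' Tabulates per-variable marginal frequencies and writes them as CSV and
#' Markdown (identical numbers), grouped by category in codebook order.
#'
#' @param input path to a records file (CSV/JSON) or a validated record
#'   data.frame.
#' @param out_dir output directory (created if needed).
#' @param codebook an `mf_codebook`.
#' @return The frequency table (invisibly).
#' @export
cmd_describe <- function(input, out_dir, codebook = builtin_codebook()) {
  records <- as_records(input, codebook)
  tab <- tabulate_marginals(records, codebook)
  ensure_dir(out_dir)
  utils::write.csv(tab, file.path(out_dir, "descriptives.csv"),
                   row.names = FALSE)
  lines <- c(sprintf("# Events and factors (N=%d)", attr(tab, "n")), "",
             "| Category | Variable | State | Count | % |", "|---|---|---|---|---|",
             sprintf("| %s | %s | %s | %d | %.1f |", tab$category,
                     tab$display, tab$state, tab$count, tab$pct))
  writeLines(lines, file.path(out_dir, "descriptives.md"))
  write_manifest(out_dir, "describe",
                 list(n = attr(tab, "n")),
                 if (is.character(input)) input else character(0))
  invisible(tab)
}

#' Structure-learning stage
#'
#' Runs the constrained search with the blacklist-refinement loop, fits
#' CPTs, assigns layers, and writes the model (JSON + DOT), a layer
#' report, the final constraint set and a manifest. Deterministic: the
#' same records, constraints, configuration and seed reproduce the output
#' files byte for byte.
#'
#' @inheritParams cmd_describe
#' @param constraints an `mf_constraints`.
#' @param config an `mf_learn_config`.
#' @param verbose log each accepted move and refinement via [message()].
#' @return The `mf_flow_model` (invisibly).
#' @export
cmd_learn <- function(input, out_dir, codebook = builtin_codebook(),
                      constraints = default_constraints(codebook),
                      config = learn_config(), verbose = FALSE) {
  records <- as_records(input, codebook)
  model <- learn_flow_model(records, codebook, constraints, config,
                            trace = if (verbose) message else NULL)
  ensure_dir(out_dir)
  bn_to_json(model$bn, file.path(out_dir, "model.json"))
  bn_to_dot(model$bn, file.path(out_dir, "model.dot"))
  lay <- model$layers
  layer_df <- data.frame(node = names(lay$layers),
                         layer = unname(lay$layers))
  layer_df <- layer_df[order(layer_df$layer, layer_df$node), , drop = FALSE]
  utils::write.csv(layer_df, file.path(out_dir, "layers.csv"),
                   row.names = FALSE)
  writeLines(c(sprintf("Flow model: %d layers", lay$n_layers),
               sprintf("Excluded (degree 0): %s",
                       paste(sort(lay$excluded), collapse = ", "))),
             file.path(out_dir, "layers.txt"))
  jsonlite::write_json(
    list(blacklist = apply(model$constraints$blacklist, 1, as.list),
         whitelist = apply(model$constraints$whitelist, 1, as.list)),
    file.path(out_dir, "constraints_final.json"),
    auto_unbox = TRUE, pretty = TRUE)
  write_manifest(out_dir, "learn",
                 list(score = config$score, threshold = config$threshold,
                      max_parents = config$max_parents,
                      smoothing_alpha = config$smoothing_alpha,
                      seed = config$seed, restarts = config$restarts,
                      n_records = nrow(records),
                      n_refinements = model$n_refinements),
                 if (is.character(input)) input else character(0))
  invisible(model)
}

#' Scenario-analysis stage
#'
#' Loads a model (JSON path, `mf_bn` or `mf_flow_model`), runs the
#' factor-suppression scenarios, and writes the report (CSV + Markdown in
#' the published table's layout) plus the factor ranking.
#'
#' @param model path to a model JSON, an `mf_bn`, or an `mf_flow_model`.
#' @param out_dir output directory.
#' @param events,factors,mode,full_grid passed to [run_scenarios()].
#' @return The `mf_scenario_result` (invisibly).
#' @export
cmd_scenario <- function(model, out_dir, events = NULL, factors = NULL,
                         mode = c("do", "condition"), full_grid = FALSE) {
  mode <- match.arg(mode)
  bn <- if (inherits(model, "mf_bn")) model
        else if (inherits(model, "mf_flow_model")) model$bn
        else bn_from_json(model)
  res <- run_scenarios(bn, events, factors, mode = mode,
                       full_grid = full_grid)
  ensure_dir(out_dir)
  write_scenario_report(res, file.path(out_dir, "scenario.csv"))
  write_scenario_report(res, file.path(out_dir, "scenario.md"))
  utils::write.csv(rank_factors(res), file.path(out_dir, "ranking.csv"),
                   row.names = FALSE)
  write_manifest(out_dir, "scenario", list(mode = mode,
                                           full_grid = full_grid),
                 if (is.character(model)) model else character(0))
  invisible(res)
}

#' Synthetic-data stage
#'
#' Generates a calibrated synthetic dataset and writes the records CSV,
#' the ground-truth network JSON and the calibration report.
#'
#' @param out_dir output directory.
#' @param n number of records.
#' @param seed integer seed.
#' @param effect_size ground-truth CPT contrast.
#' @param codebook an `mf_codebook`.
#' @return The [generate_dataset()] result (invisibly).
#' @export
cmd_synth <- function(out_dir, n = 119L, seed = 1L, effect_size = 0.3,
                      codebook = builtin_codebook()) {
  spec <- truth_spec(codebook, effect_size = effect_size, n = n, seed = seed)
  gen <- generate_dataset(spec)
  ensure_dir(out_dir)
  write_records(gen$records, file.path(out_dir, "records.csv"), codebook)
  bn_to_json(gen$bn, file.path(out_dir, "truth.json"))
  utils::write.csv(gen$report, file.path(out_dir, "calibration.csv"),
                   row.names = FALSE)
  write_manifest(out_dir, "synth",
                 list(n = n, seed = seed, effect_size = effect_size))
  invisible(gen)
}

#' Run the full pipeline on synthetic data
#'
#' synth -> describe -> learn -> scenario, each stage in its own
#' subdirectory of `out_dir`.
#'
#' @inheritParams cmd_synth
#' @param config an `mf_learn_config`.
#' @return Named list of the stage results (invisibly).
#' @export
run_pipeline <- function(out_dir, n = 119L, seed = 1L, effect_size = 0.3,
                         codebook = builtin_codebook(),
                         config = learn_config()) {
  gen <- cmd_synth(file.path(out_dir, "synth"), n, seed, effect_size,
                   codebook)
  tab <- cmd_describe(gen$records, file.path(out_dir, "describe"), codebook)
  model <- cmd_learn(gen$records, file.path(out_dir, "learn"), codebook,
                     config = config)
  res <- cmd_scenario(model, file.path(out_dir, "scenario"))
  invisible(list(synth = gen, describe = tab, learn = model,
                 scenario = res))
}
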