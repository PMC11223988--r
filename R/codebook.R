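# Fixed variable taxonomy for nurse medication-error incident reports:
# 10 error events plus 24 contributing factors in four categories
# (attributional, system, conditional, knowledge/behavioral).

NODE_CATEGORIES <- c("event", "attributional", "system", "conditional",
                     "knowledge_behavioral")
BINARY_STATES <- c("absent", "present")

node_def <- function(name, display, category, states, description,
                     counts = NULL, default_marginal = NULL) {
  stopifnot(length(states) >= 2L, !anyDuplicated(states),
            category %in% NODE_CATEGORIES)
  if (!is.null(counts)) stopifnot(length(counts) == length(states))
  if (!is.null(default_marginal)) {
    stopifnot(length(default_marginal) == length(states),
              abs(sum(default_marginal) - 1) < 1e-9)
  }
  structure(list(name = name, display = display, category = category,
                 states = states, description = description,
                 counts = counts, default_marginal = default_marginal),
            class = "mf_node_def")
}

# Convenience: binary incident-factor node with a published "present" count
# out of N = 119 (NA when the source table leaves the cell blank).
binary_node <- function(name, display, category, description,
                        present_count = NA_integer_,
                        default_present = NULL) {
  counts <- if (is.na(present_count)) NULL else
    c(119L - as.integer(present_count), as.integer(present_count))
  dm <- if (is.null(default_present)) NULL else
    c(1 - default_present, default_present)
  node_def(name, display, category, BINARY_STATES, description,
           counts = counts, default_marginal = dm)
}

#' Built-in codebook of medication-error events and factors
#'
#' Returns the fixed 34-variable codebook used throughout the package:
#' 10 error-event variables and 24 contributing-factor variables grouped
#' into attributional (2), system (1), conditional (8) and
#' knowledge/behavioral (13) categories. Variable names are ASCII
#' snake_case identifiers suitable for file headers; the original display
#' labels are kept in the `display` field. Binary variables use the states
#' `absent`/`present`; nurse experience, tenure in the current work
#' setting, work time and patient age are multi-state bands.
#'
#' Where available, each node carries the published per-state counts from
#' the N = 119 incident-report study that the package emulates; these are
#' used as calibration targets by the synthetic-data generator and to
#' construct [reference_records()]. Two conditional factors (night shift,
#' patient age) have no published counts; they carry documented default
#' marginals instead (see [codebook_marginals()]).
#'
#' @return An object of class `mf_codebook`: a list of node definitions,
#'   each with fields `name`, `display`, `category`, `states`,
#'   `description`, `counts` (per-state, or `NULL`) and
#'   `default_marginal`.
#' @examples
#' cb <- builtin_codebook()
#' length(cb$nodes)
#' table(node_categories(cb))
#' @export
builtin_codebook <- function() {
  ev <- function(name, display, count, desc)
    binary_node(name, display, "event", desc, present_count = count)
  kb <- function(name, display, count, desc)
    binary_node(name, display, "knowledge_behavioral", desc,
                present_count = count)

  nodes <- list(
    ## -- events ------------------------------------------------------------
    ev("wrong_dose", "Wrong dose", 43L,
       "Administered the wrong dose of medication (over- or underdosing, mostly infusions)."),
    ev("wrong_patient", "Wrong patient", 22L,
       "Administered medicine to the wrong patient, mostly during oral administration."),
    ev("improper_mixing", "Improper mixing", 15L,
       "Performed improper mixing of intravenous solutions."),
    ev("wrong_or_unnecessary_administration", "Wrong or unnecessary administration", 13L,
       "Administered a different medication than ordered, or one that was unnecessary."),
    ev("overlooking_contraindication", "Overlooking contraindication", 11L,
       "Missed a contraindicated medication."),
    ev("accidental_ingestion_overdose", "Accidental ingestion/overdose", 7L,
       "Patient accidentally ingested or overdosed."),
    ev("incorrect_storage", "Incorrect storage", 6L,
       "Stored medicine using an incorrect storage method."),
    ev("wrong_timing", "Wrong timing", 4L,
       "Administered medicine at the wrong time."),
    ev("failure_to_discontinue_medication", "Failure to discontinue medication", 4L,
       "Failed to discontinue a medication."),
    ev("wrong_route", "Wrong route", 2L,
       "Administered medicine by the wrong route."),

    ## -- attributional factors (no parents by construction) ----------------
    node_def("years_registered_nurse", "Years as registered nurse",
             "attributional", c("<5", "5-9", ">=10"),
             "Experience as a registered nurse, in 5-year bands.",
             counts = c(39L, 28L, 52L)),
    node_def("years_current_work_setting", "Years in current work setting",
             "attributional", c("<1", "1-3", ">3"),
             "Tenure in the current ward, in stages of task independence.",
             counts = c(33L, 36L, 50L)),

    ## -- system factor ------------------------------------------------------
    binary_node("failure_to_detect_by_electronic_system",
                "Failure to detect by electronic system", "system",
                "Electronic medical record system not equipped to detect the error.",
                present_count = 7L),

    ## -- conditional factors -------------------------------------------------
    binary_node("worked_in_holiday", "Worked in holiday", "conditional",
                "Workday was a holiday.", present_count = 24L),
    node_def("work_time", "Work time", "conditional",
             c("09:00-16:00", "16:00-21:00", "21:00-09:00"),
             "Work time band, following the patient's day and the nurse's duties.",
             counts = c(54L, 31L, 34L)),
    binary_node("night_shift", "Night shift", "conditional",
                "Error occurred during the night shift rather than the day shift.",
                default_present = 0.30),
    node_def("patient_age", "Patient age (yr)", "conditional",
             c("<20", "20-59", ">=60"),
             "Age band of the patient associated with the error.",
             default_marginal = c(0.10, 0.30, 0.60)),
    binary_node("time_pressure", "Time pressure", "conditional",
                "Time pressure from sudden emergencies or multiple concurrent tasks.",
                present_count = 42L),
    binary_node("sudden_change_in_patient_schedule",
                "Sudden change in patient's schedule", "conditional",
                "Sudden change in the examination or treatment schedule.",
                present_count = 10L),
    binary_node("failure_of_doctors_orders", "Failure of doctor's orders",
                "conditional", "The doctor's orders themselves failed.",
                present_count = 10L),
    binary_node("patients_not_following_instructions",
                "Patients who do not follow instructions", "conditional",
                "Patient did not follow the instructions of health-care professionals.",
                present_count = 13L),

    ## -- knowledge/behavioral factors ---------------------------------------
    kb("failure_to_confirm_5_rights", "Failure to confirm the 5 rights", 59L,
       "Failure to check the 5 rights (patient, drug, dose, route, time)."),
    kb("assumptions_and_forgetfulness", "Assumptions and forgetfulness", 47L,
       "Assumed or forgot instructions and orders."),
    kb("invalid_double_check", "Invalid double check", 40L,
       "Mutual double-checking between nurses was invalid."),
    kb("improper_use_of_instruments_equipment",
       "Improper use of instruments and equipment", 35L,
       "Use of instruments/equipment induced the error (e.g. several patients' medications in one tray)."),
    kb("insufficient_knowledge_of_medications",
       "Insufficient knowledge of medications", 27L,
       "Insufficient knowledge of the medications involved."),
    kb("unfamiliarity_with_operations", "Unfamiliarity with operations of medications", 23L,
       "Did not know how to handle the medications properly due to unfamiliarity."),
    kb("failure_of_information_communication", "Failure of information communication", 23L,
       "Discrepancies in communication when conveying information."),
    kb("improper_handling_of_medications", "Improper handling of medications", 13L,
       "Handled the medicine in the wrong way."),
    kb("failure_of_monitoring", "Failure of monitoring", 13L,
       "Monitoring failure that could plausibly have been avoided."),
    kb("task_interruption", "Task interruption", 11L,
       "Task was interrupted when the error occurred."),
    kb("non_reconfirming_doctors_orders",
       "Non-reconfirming of inappropriate doctor's orders", 10L,
       "Did not re-check orders the nurse already felt were inappropriate."),
    kb("lack_of_explanation_to_patients", "Lack of explanation to patients", 4L,
       "Insufficient explanation about the medication to the patient."),
    kb("miscalculation", "Miscalculation", 4L,
       "Miscalculated the appropriate dosage.")
  )
  names(nodes) <- vapply(nodes, `[[`, "", "name")
  cb <- structure(list(nodes = nodes, n_reports = 119L),
                  class = "mf_codebook")
  validate_codebook(cb, builtin = TRUE)
  cb
}

validate_codebook <- function(cb, builtin = FALSE) {
  stopifnot(inherits(cb, "mf_codebook"))
  nm <- node_names(cb)
  if (anyDuplicated(nm)) stop("duplicate node names in codebook")
  if (builtin) {
    tab <- table(factor(node_categories(cb), levels = NODE_CATEGORIES))
    expected <- c(event = 10L, attributional = 2L, system = 1L,
                  conditional = 8L, knowledge_behavioral = 13L)
    if (!all(tab[names(expected)] == expected))
      stop("codebook category counts do not match the fixed taxonomy")
  }
  invisible(cb)
}

#' Construct an ad-hoc codebook
#'
#' Builds an `mf_codebook` over arbitrary variables, mainly for
#' simulation studies and tests on small networks. All variables default
#' to binary `absent`/`present`.
#'
#' @param names character vector of node names.
#' @param categories category per node (recycled), one of `event`,
#'   `attributional`, `system`, `conditional`, `knowledge_behavioral`.
#' @param states named list of state vectors overriding the binary
#'   default for specific nodes.
#' @return An `mf_codebook`.
#' @export
codebook_from_nodes <- function(names,
                                categories = "conditional",
                                states = list()) {
  categories <- rep_len(categories, length(names))
  nodes <- lapply(seq_along(names), function(i)
    node_def(names[[i]], names[[i]], categories[[i]],
             states[[names[[i]]]] %||% BINARY_STATES, ""))
  names(nodes) <- names
  validate_codebook(structure(list(nodes = nodes, n_reports = NA_integer_),
                              class = "mf_codebook"))
}

#' @rdname builtin_codebook
#' @param codebook an `mf_codebook` object.
#' @export
node_names <- function(codebook) names(codebook$nodes)

#' @rdname builtin_codebook
#' @export
node_categories <- function(codebook) {
  vapply(codebook$nodes, `[[`, "", "category")
}

#' @rdname builtin_codebook
#' @export
node_states <- function(codebook) {
  lapply(codebook$nodes, `[[`, "states")
}

#' @rdname builtin_codebook
#' @export
display_names <- function(codebook) {
  vapply(codebook$nodes, `[[`, "", "display")
}

is_binary_node <- function(nd) identical(nd$states, BINARY_STATES)

#' Target marginal distributions for every codebook variable
#'
#' Per-state probabilities derived from the published frequency
#' distribution of the N = 119 incident-report study (exact count
#' fractions, not rounded percentages). For the two conditional factors
#' whose counts were not published (night shift; patient age), documented
#' defaults are used: night shift present 30%; patient age bands
#' `<20`/`20-59`/`>=60` at 10/30/60%. These marginals are the calibration
#' targets of the synthetic-data generator.
#'
#' @param codebook an `mf_codebook`, normally [builtin_codebook()].
#' @return Named list: for each node, a named numeric vector of per-state
#'   probabilities summing to 1.
#' @export
codebook_marginals <- function(codebook = builtin_codebook()) {
  out <- lapply(codebook$nodes, function(nd) {
    p <- if (!is.null(nd$counts)) nd$counts / sum(nd$counts) else
      nd$default_marginal
    if (is.null(p))
      stop("node '", nd$name, "' has neither counts nor a default marginal")
    stats::setNames(p, nd$states)
  })
  out
}

#' Published per-state counts, as a data frame
#'
#' One row per node and state with the published count out of N = 119
#' (`NA` where the source left the cell blank) and the percentage rounded
#' to one decimal, the convention used for all descriptive reporting in
#' this package.
#'
#' @inheritParams codebook_marginals
#' @return data.frame with columns `node`, `display`, `category`, `state`,
#'   `count`, `pct`.
#' @export
codebook_counts <- function(codebook = builtin_codebook()) {
  rows <- lapply(codebook$nodes, function(nd) {
    cnt <- if (is.null(nd$counts)) rep(NA_integer_, length(nd$states)) else
      nd$counts
    data.frame(node = nd$name, display = nd$display, category = nd$category,
               state = nd$states, count = cnt,
               pct = round(cnt / codebook$n_reports * 100, 1),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export the codebook as a JSON document
#'
#' @inheritParams codebook_marginals
#' @param path file to write; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
codebook_to_json <- function(codebook = builtin_codebook(), path = NULL) {
  doc <- lapply(unname(codebook$nodes), function(nd) {
    list(name = nd$name, display = nd$display, category = nd$category,
         states = nd$states, description = nd$description)
  })
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @export
print.mf_codebook <- function(x, ...) {
  tab <- table(factor(node_categories(x), levels = NODE_CATEGORIES))
  cat("Incident-report codebook:", length(x$nodes), "variables\n")
  for (cat_name in names(tab))
    cat(sprintf("  %-22s %d\n", cat_name, tab[[cat_name]]))
  invisible(x)
}
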