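# Incident-report record I/O, validation and descriptive tabulation.
# A record set is a plain data.frame with one character column per
# codebook variable and one row per report.

#' Validate incident-report records against a codebook
#'
#' Checks that every codebook variable is present as a column, that every
#' cell holds one of the variable's declared states (missing values are
#' rejected, not imputed), and that every record documents at least one
#' error event in state `present` (an incident report must report an
#' incident; several events per report are allowed).
#'
#' @param records data.frame of records, columns named by codebook node
#'   names, values being state labels.
#' @param codebook an `mf_codebook`.
#' @return `records`, invisibly, with columns reordered to codebook order.
#' @export
validate_records <- function(records, codebook = builtin_codebook()) {
  stopifnot(is.data.frame(records))
  nm <- node_names(codebook)
  unknown <- setdiff(names(records), nm)
  if (length(unknown))
    stop("unknown column(s) not in the codebook: ",
         paste(unknown, collapse = ", "))
  missing_cols <- setdiff(nm, names(records))
  if (length(missing_cols))
    stop("missing codebook column(s): ", paste(missing_cols, collapse = ", "))
  records <- records[, nm, drop = FALSE]
  states <- node_states(codebook)
  for (v in nm) {
    col <- as.character(records[[v]])
    bad <- which(is.na(col) | !(col %in% states[[v]]))
    if (length(bad))
      stop(sprintf("illegal state '%s' for node '%s' in row %d",
                   as.character(records[[v]][bad[1]]), v, bad[1]))
    records[[v]] <- col
  }
  ev <- nm[node_categories(codebook) == "event"]
  if (nrow(records) > 0 && length(ev)) {
    any_event <- Reduce(`|`, lapply(ev, function(v) records[[v]] == "present"))
    if (any(!any_event))
      stop(sprintf(paste0("row %d has no event in state 'present'; every ",
                          "incident record must document at least one event"),
                   which(!any_event)[1]))
  }
  rownames(records) <- NULL
  invisible(records)
}

normalize_binary_levels <- function(records, codebook) {
  states <- node_states(codebook)
  for (v in intersect(names(records), node_names(codebook))) {
    if (identical(states[[v]], BINARY_STATES)) {
      col <- as.character(records[[v]])
      col[col %in% c("0", "FALSE", "false")] <- "absent"
      col[col %in% c("1", "TRUE", "true")] <- "present"
      records[[v]] <- col
    } else {
      records[[v]] <- as.character(records[[v]])
    }
  }
  records
}

#' Read incident-report records from CSV or JSON
#'
#' CSV files must have a header row of codebook node names; JSON files
#' must hold an array of flat objects with the same keys. Binary columns
#' accept `0`/`1` as well as `absent`/`present`; both spellings are
#' normalized to state labels. All records are validated (see
#' [validate_records()]); malformed input is a hard error naming the
#' offending column, row or invariant.
#'
#' @param path file to read.
#' @param codebook an `mf_codebook`.
#' @param format `"csv"`, `"json"`, or `NULL` to infer from the extension.
#' @return data.frame of validated records in codebook column order.
#' @export
read_records <- function(path, codebook = builtin_codebook(), format = NULL) {
  format <- format %||% infer_format(path)
  records <- switch(format,
    csv = utils::read.csv(path, colClasses = "character",
                          check.names = FALSE),
    json = {
      x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
      if (!is.data.frame(x)) x <- as.data.frame(x, stringsAsFactors = FALSE)
      x
    },
    stop("unsupported record format: ", format)
  )
  records <- normalize_binary_levels(records, codebook)
  validate_records(records, codebook)
}

#' Write incident-report records to CSV or JSON
#'
#' Lossless counterpart of [read_records()]: a write followed by a read
#' returns identical records, in either format.
#'
#' @param records validated record data.frame.
#' @param path file to write.
#' @param codebook an `mf_codebook`.
#' @param format `"csv"`, `"json"`, or `NULL` to infer from the extension.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, codebook = builtin_codebook(),
                          format = NULL) {
  if (nrow(records) > 0) records <- validate_records(records, codebook)
  format <- format %||% infer_format(path)
  switch(format,
    csv = utils::write.csv(records, path, row.names = FALSE, quote = FALSE),
    json = jsonlite::write_json(records, path, dataframe = "rows"),
    stop("unsupported record format: ", format)
  )
  invisible(path)
}

infer_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "json")) ext else
    stop("cannot infer record format from extension of '", path, "'")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tabulate per-variable marginal frequencies
#'
#' Descriptive frequency table in the layout of the published study:
#' for binary variables the count and percentage of the `present` state;
#' for multi-state variables one row per state. Percentages are
#' `count / N * 100` rounded to one decimal.
#'
#' @param records validated record data.frame with at least one row.
#' @param codebook an `mf_codebook`.
#' @return data.frame with columns `node`, `display`, `category`, `state`,
#'   `count`, `pct`; attribute `n` holds the record count.
#' @export
tabulate_marginals <- function(records, codebook = builtin_codebook()) {
  if (nrow(records) == 0) stop("cannot tabulate an empty record set")
  records <- validate_records(records, codebook)
  n <- nrow(records)
  rows <- lapply(codebook$nodes, function(nd) {
    st <- if (is_binary_node(nd)) "present" else nd$states
    cnt <- vapply(st, function(s) sum(records[[nd$name]] == s), 0L)
    data.frame(node = nd$name, display = nd$display, category = nd$category,
               state = st, count = as.integer(cnt),
               pct = round(cnt / n * 100, 1),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n") <- n
  out
}

#' Deterministic 119-record reference dataset
#'
#' Constructs a record set whose per-variable marginal counts reproduce
#' the published frequency distribution of the N = 119 incident-report
#' study exactly. Events are laid out in consecutive wrapped blocks so
#' that every record carries at least one `present` event; factor columns
#' use staggered wrapped blocks (a deterministic offset per variable) so
#' that the fixture is not a degenerate all-columns-aligned design. Only
#' the marginals are meaningful — the joint structure of this fixture is
#' arbitrary, and it is intended for testing descriptive tabulation, not
#' for structure learning. The two variables without published counts are
#' filled from their documented default marginals (largest-remainder
#' rounding of counts).
#'
#' @param codebook an `mf_codebook`, normally [builtin_codebook()].
#' @return data.frame of 119 validated records.
#' @export
reference_records <- function(codebook = builtin_codebook()) {
  n <- codebook$n_reports
  recs <- as.data.frame(
    lapply(codebook$nodes, function(nd) rep(nd$states[[1]], n)),
    stringsAsFactors = FALSE)
  names(recs) <- node_names(codebook)

  wrap <- function(start, len) ((start - 1 + seq_len(len) - 1) %% n) + 1

  # events: consecutive blocks covering rows 1..n (counts sum to 127 > 119)
  ev_nodes <- codebook$nodes[node_categories(codebook) == "event"]
  pos <- 1L
  for (nd in ev_nodes) {
    k <- nd$counts[[2]]
    recs[wrap(pos, k), nd$name] <- "present"
    pos <- pos + k
  }

  # factors: per-variable staggered offsets, exact counts per state
  fa_nodes <- codebook$nodes[node_categories(codebook) != "event"]
  offset <- 1L
  for (nd in fa_nodes) {
    counts <- nd$counts %||% largest_remainder_counts(nd$default_marginal, n)
    pos <- offset
    for (s in seq_along(nd$states)) {
      k <- counts[[s]]
      if (k > 0) recs[wrap(pos, k), nd$name] <- nd$states[[s]]
      pos <- pos + k
    }
    offset <- offset + 17L
  }
  validate_records(recs, codebook)
}

largest_remainder_counts <- function(p, n) {
  raw <- p * n
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}
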