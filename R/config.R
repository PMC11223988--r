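# Constraint-set file interface: a JSON or YAML document of the form
#   {"blacklist": [["parent","child"], ...],
#    "whitelist": [["parent","child"], ...]}
# Category rules are part of the package's taxonomy and are not read
# from files; the default rules are attached on load.

#' Read a constraint set from a JSON or YAML file
#'
#' @param path file ending in `.json`, `.yaml` or `.yml`.
#' @param category_rules rules to attach, see [default_category_rules()].
#' @return An `mf_constraints`.
#' @export
read_constraints <- function(path,
                             category_rules = default_category_rules()) {
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML constraint files")
    yaml::read_yaml(path)
  } else stop("unsupported constraints format: ", ext)
  to_edges <- function(x) {
    if (!length(x)) return(NULL)
    do.call(rbind, lapply(x, function(e) unlist(e)[1:2]))
  }
  constraint_set(blacklist = to_edges(doc$blacklist),
                 whitelist = to_edges(doc$whitelist),
                 category_rules = category_rules)
}

#' Write a constraint set to a JSON file
#'
#' @param constraints an `mf_constraints`.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_constraints <- function(constraints, path) {
  doc <- list(
    blacklist = unname(apply(constraints$blacklist, 1,
                             function(r) as.list(unname(r)))),
    whitelist = unname(apply(constraints$whitelist, 1,
                             function(r) as.list(unname(r)))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
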