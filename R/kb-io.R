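# On-disk knowledge-base format.
#
# Canonical dialect is YAML (JSON is accepted as an equivalent encoding).
# One document describes one graph:
#
#   name: lpr
#   sub: true               # optional; single-disease module
#   variables:
#   - {id: B23, kind: B, states: 2, label: ..., prior: [0.97, 0.03]}
#   links:
#   - child: X21
#     parent: BX23
#     r: 1.0
#     strength: [[0.0, 0.5]]     # rows = abnormal child states, cols = parent states
#   gates:
#   - {id: SG23, remnant: 0, rows: [{state: 1, expr: X74=1}]}
#   sa:
#   - {disease: B23, bx: BX23, gate: SG23, factors: [1.0, 10.0]}
#
# A knowledge base may also be a directory of <disease>.yaml sub-graph
# files listed by an index.yaml ({name: ..., subgraphs: [lpr.yaml, ...]});
# loading such a directory merges the modules.

kb_to_list <- function(kb) {
  list(
    name = kb$name,
    sub = inherits(kb, "ducg_sub"),
    variables = lapply(unname(kb$variables), function(v) {
      out <- list(id = v$id, kind = v$kind, states = v$n_states)
      if (nzchar(v$label)) out$label <- v$label
      if (!is.null(v$prior)) out$prior <- as.numeric(v$prior)
      out
    }),
    links = lapply(kb$links, function(l) {
      list(child = l$child, parent = l$parent, r = l$r,
           strength = lapply(seq_len(nrow(l$strength)),
                             function(i) as.numeric(l$strength[i, ])))
    }),
    gates = lapply(unname(kb$gates), function(g) {
      list(id = g$id, remnant = g$remnant,
           rows = lapply(g$rows, function(row)
             list(state = row$state, expr = row$expr)))
    }),
    sa = lapply(unname(kb$sa), function(s) {
      list(disease = s$disease, bx = s$bx, gate = s$gate,
           factors = as.numeric(s$factors))
    })
  )
}

require_field <- function(record, field, where) {
  if (is.null(record[[field]]))
    stop("parse error in ", where, ": missing field '", field, "'",
         call. = FALSE)
  record[[field]]
}

kb_from_list <- function(doc, where = "knowledge base", check = TRUE) {
  if (is.null(doc$variables) || length(doc$variables) == 0L)
    stop("parse error in ", where, ": no variables declared (a knowledge ",
         "base must contain at least one disease root)", call. = FALSE)
  variables <- lapply(doc$variables, function(v)
    ducg_variable(require_field(v, "id", where),
                  require_field(v, "kind", where),
                  n_states = v$states %||% 2L,
                  label = v$label %||% "",
                  prior = v$prior))
  links <- lapply(doc$links %||% list(), function(l) {
    strength <- require_field(l, "strength", where)
    if (is.list(strength))
      strength <- do.call(rbind, lapply(strength, as.numeric))
    ducg_link(require_field(l, "child", where),
              require_field(l, "parent", where),
              r = l$r %||% 1,
              strength = strength)
  })
  gates <- lapply(doc$gates %||% list(), function(g)
    ducg_gate(require_field(g, "id", where),
              rows = require_field(g, "rows", where),
              remnant = g$remnant %||% 0L))
  sa <- lapply(doc$sa %||% list(), function(s)
    ducg_sa(require_field(s, "disease", where),
            require_field(s, "bx", where),
            require_field(s, "gate", where),
            factors = require_field(s, "factors", where)))
  kb <- ducg_kb(variables, links, gates, sa,
                name = doc$name %||% "kb",
                sub = isTRUE(doc$sub), check = FALSE)
  if (check) {
    errs <- validation_errors(validate_kb(kb))
    if (length(errs) > 0L)
      stop("validation error in ", where, ":\n  ",
           paste(errs, collapse = "\n  "), call. = FALSE)
  }
  kb
}

read_kb_document <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  else yaml::read_yaml(path)
}

#' Load a knowledge base from disk
#'
#' Reads a YAML or JSON knowledge-base document, or a directory of
#' sub-graph documents with an `index.yaml`, validates it, and (for a
#' directory) merges the modules into a complete graph.
#'
#' @param path File or directory path.
#' @param merge For directory input: merge the sub-graphs (default) or
#'   return the list of sub-DUCGs.
#' @return A `ducg` object, or a list of them when `merge = FALSE`.
#' @seealso [write_kb()], [merge_subgraphs()], [validate_kb()]
#' @examples
#' path <- system.file("extdata", "kb", "lpr.yaml", package = "ducgdx")
#' kb <- load_kb(path)
#' @export
load_kb <- function(path, merge = TRUE) {
  if (dir.exists(path)) {
    index_path <- file.path(path, "index.yaml")
    if (!file.exists(index_path))
      stop("knowledge-base directory ", path, " has no index.yaml",
           call. = FALSE)
    index <- yaml::read_yaml(index_path)
    files <- require_field(index, "subgraphs", index_path)
    parts <- lapply(files, function(f)
      kb_from_list(read_kb_document(file.path(path, f)), where = f))
    if (!merge) return(parts)
    return(merge_subgraphs(parts, name = index$name %||% basename(path)))
  }
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  kb_from_list(read_kb_document(path), where = path)
}

#' Write a knowledge base to disk
#'
#' Serializes a knowledge base to the YAML (canonical) or JSON dialect.
#' A written file loads back to a structurally identical graph
#' ([kb_identical()]).
#'
#' @param kb A `ducg` object.
#' @param path Output path; the extension selects the dialect unless
#'   `format` is given.
#' @param format `"yaml"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_kb <- function(kb, path, format = c("auto", "yaml", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "yaml"
  doc <- kb_to_list(kb)
  if (format == "json")
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(doc, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
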