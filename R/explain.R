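# Per-hypothesis graphic interpretation: which abnormal evidence the
# hypothesis explains, which it cannot (isolated), which normal evidence
# counts against it, which risk factors raise its prior, and the causal
# paths from the hypothesis to each explained finding.

#' Interpret the evidence under one hypothesis
#'
#' Partitions the case evidence from the point of view of a single
#' hypothesis, by pure graph reachability on the decomposed view (model
#' parameters play no role): abnormal evidence with a causal path from the
#' hypothesis root is \emph{explained}; abnormal evidence without one is
#' \emph{isolated}; normal evidence on manifestations linked to the
#' hypothesis is \emph{negative} evidence; observed risk factors wired
#' into the hypothesis's logic gate are listed separately. Explained and
#' isolated evidence together are exactly the abnormal evidence E' (risk
#' factors aside).
#'
#' @param view A `ducg_view` from [decompose()].
#' @param ev Evidence; defaults to the view's stored evidence.
#' @param max_paths Cap on enumerated causal paths per explained finding
#'   (shortest first, default 10).
#' @return A `ducg_interpretation` list with elements `disease`, `state`,
#'   `explained`, `isolated`, `negative`, `risk_factors`, `paths`.
#' @export
interpret <- function(view, ev = view$evidence, max_paths = 10L) {
  stopifnot(inherits(view, "ducg_view"))
  if (!inherits(ev, "ducg_evidence")) ev <- ducg_evidence(ev)
  kb <- view$kb
  sp <- split_risk_evidence(kb, ev)
  obs <- sp$net$observations
  obs <- obs[names(obs) %in% names(kb$variables)]
  graph <- links_graph(kb)
  reach <- links_reachable(graph, view$root)

  abnormal <- names(obs[obs != 0L])
  explained <- intersect(abnormal, reach)
  isolated <- setdiff(abnormal, explained)
  negative <- intersect(names(obs[obs == 0L]), reach)

  gate_vars <- character(0)
  s <- kb$sa[[view$disease]]
  if (!is.null(s)) {
    g <- kb$gates[[s$gate]]
    gate_vars <- unique(unlist(lapply(g$rows, function(row)
      gate_expr_vars(row$expr))))
  }
  risk_factors <- intersect(names(sp$risk), gate_vars)

  paths <- setNames(lapply(explained, function(target) {
    found <- igraph::all_simple_paths(graph, from = view$root, to = target,
                                      mode = "out")
    found <- found[order(lengths(found))]
    lapply(utils::head(found, max_paths), function(p) names(p))
  }), explained)

  structure(list(disease = view$disease, state = view$state,
                 root = view$root, explained = explained,
                 isolated = isolated, negative = negative,
                 risk_factors = risk_factors, paths = paths,
                 observations = obs, risk = sp$risk),
            class = "ducg_interpretation")
}

#' @export
print.ducg_interpretation <- function(x, ...) {
  cat(render_interpretation(x, format = "text"))
  invisible(x)
}

#' Render an interpretation as DOT or text
#'
#' DOT output styles explained, isolated and negative evidence and risk
#' factors distinctly (and omits empty groups); text output is a stable,
#' diffable report listing the causal paths from the hypothesis to each
#' explained finding in declared order.
#'
#' @param interp A `ducg_interpretation`.
#' @param format `"DOT"` or `"text"`.
#' @return A single string.
#' @export
render_interpretation <- function(interp, format = c("text", "DOT")) {
  format <- match.arg(format)
  if (format == "text") return(render_interpretation_text(interp))
  render_interpretation_dot(interp)
}

render_interpretation_text <- function(x) {
  fmt_set <- function(ids, states) {
    if (length(ids) == 0L) return("  (none)\n")
    paste0(vapply(ids, function(id)
      sprintf("  %s = %d\n", id, states[[id]]), character(1)), collapse = "")
  }
  out <- sprintf("hypothesis %s,%d (root %s)\n", x$disease, x$state, x$root)
  out <- paste0(out, "explained abnormal evidence:\n",
                fmt_set(x$explained, x$observations),
                "isolated abnormal evidence:\n",
                fmt_set(x$isolated, x$observations),
                "negative (normal) evidence:\n",
                fmt_set(x$negative, x$observations),
                "risk factors:\n", fmt_set(x$risk_factors, as.list(x$risk)))
  out <- paste0(out, "causal paths:\n")
  if (length(x$paths) == 0L) return(paste0(out, "  (none)\n"))
  for (target in names(x$paths))
    for (p in x$paths[[target]])
      out <- paste0(out, "  ", paste(p, collapse = " -> "), "\n")
  out
}

dot_quote <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')

render_interpretation_dot <- function(x) {
  lines <- c(sprintf("digraph %s {", dot_quote(paste0(x$disease, "_", x$state))),
             "  rankdir=TB;",
             sprintf("  %s [shape=doublecircle, style=filled, fillcolor=lightpink, label=%s];",
                     dot_quote(x$root),
                     dot_quote(sprintf("%s,%d", x$disease, x$state))))
  style <- function(ids, shape, color, tag) {
    if (length(ids) == 0L) return(character(0))  # empty group: no cluster
    c(sprintf("  subgraph %s {", dot_quote(paste0("cluster_", tag))),
      sprintf("    label=%s;", dot_quote(tag)),
      vapply(ids, function(id)
        sprintf("    %s [shape=%s, style=filled, fillcolor=%s];",
                dot_quote(id), shape, color), character(1)),
      "  }")
  }
  lines <- c(lines,
             style(x$explained, "ellipse", "lightyellow", "explained"),
             style(x$isolated, "ellipse", "lightgrey", "isolated"),
             style(x$negative, "ellipse", "white", "negative"),
             style(x$risk_factors, "box", "lightblue", "risk"))
  edges <- character(0)
  for (target in names(x$paths))
    for (p in x$paths[[target]])
      for (i in seq_len(length(p) - 1L))
        edges <- c(edges, sprintf("  %s -> %s;", dot_quote(p[i]),
                                  dot_quote(p[i + 1L])))
  for (rf in x$risk_factors)
    edges <- c(edges, sprintf("  %s -> %s [style=dashed];", dot_quote(rf),
                              dot_quote(x$root)))
  paste(c(lines, unique(edges), "}"), collapse = "\n")
}

#' Export a whole knowledge base as DOT
#'
#' @param kb A `ducg`.
#' @return A DOT document (string) of the causal graph, diseases boxed.
#' @export
render_kb_dot <- function(kb) {
  kinds <- vapply(kb$variables, function(v) v$kind, character(1))
  node <- function(id) {
    shape <- switch(kinds[[id]], B = "box", BX = "box", SG = "diamond",
                    D = "octagon", "ellipse")
    sprintf("  %s [shape=%s];", dot_quote(id), shape)
  }
  edges <- kb_edges(kb)
  paste(c(sprintf("digraph %s {", dot_quote(kb$name)),
          vapply(names(kb$variables), node, character(1)),
          sprintf("  %s -> %s;", vapply(edges$from, dot_quote, character(1)),
                  vapply(edges$to, dot_quote, character(1))),
          "}"), collapse = "\n")
}

#' JSON serialization of an interpretation
#'
#' @param interp A `ducg_interpretation`.
#' @return A JSON string.
#' @export
interpretation_json <- function(interp) {
  jsonlite::toJSON(list(
    hypothesis = list(disease = interp$disease, state = interp$state),
    explained = interp$explained, isolated = interp$isolated,
    negative = interp$negative, risk_factors = interp$risk_factors,
    paths = interp$paths), auto_unbox = TRUE, pretty = TRUE)
}
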