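finding <- function(level, code, message) {
  list(level = level, code = code, message = message)
}

#' Validate a knowledge base
#'
#' Checks a structurally parsed knowledge base for semantic errors and
#' suspicious constructs. Errors: missing disease root, dangling variable
#' references, strength-matrix dimension mismatches, cycles in the causal
#' graph, conditional-probability overflow (for some child and some joint
#' parent-state assignment the abnormal mass exceeds 1, so the residual
#' normal-state probability would be negative), sa records whose
#' remnant-state factor is not 1. Warnings: variables unreachable from any
#' disease root, diseases with no manifestations.
#'
#' The overflow check is exact without enumerating joint parent states:
#' the abnormal mass `sum_i (r_i / r) * colsum_i(j_i)` is separable over
#' parents, so its maximum is attained by maximizing each parent's column
#' sum independently.
#'
#' @param kb A `ducg` object.
#' @return A list of findings, each `list(level, code, message)`; empty
#'   when the knowledge base is clean.
#' @examples
#' validate_kb(lpr_subducg())  # list()
#' @export
validate_kb <- function(kb) {
  findings <- list()
  add <- function(level, code, msg)
    findings[[length(findings) + 1L]] <<- finding(level, code, msg)
  ids <- names(kb$variables)
  kinds <- vapply(kb$variables, function(v) v$kind, character(1))

  if (!any(kinds == "B"))
    add("error", "no_disease_root",
        "a knowledge base must contain at least one disease root (kind B)")

  # dangling references and strength dimensions
  for (l in kb$links) {
    for (ref in c(l$child, l$parent)) {
      if (!ref %in% ids) {
        add("error", "dangling_reference",
            sprintf("link %s -> %s references undeclared variable %s",
                    l$parent, l$child, ref))
      }
    }
    if (all(c(l$child, l$parent) %in% ids)) {
      nc <- kb$variables[[l$child]]$n_states
      np <- kb$variables[[l$parent]]$n_states
      if (nrow(l$strength) != nc - 1L || ncol(l$strength) != np)
        add("error", "strength_dimension",
            sprintf("link %s -> %s: strength must be %d x %d, got %d x %d",
                    l$parent, l$child, nc - 1L, np,
                    nrow(l$strength), ncol(l$strength)))
    }
  }

  for (g in kb$gates) {
    if (!g$id %in% ids || kinds[g$id] != "SG")
      add("error", "dangling_reference",
          sprintf("gate %s is not declared as an SG variable", g$id))
    for (v in unique(unlist(lapply(g$rows, function(row) gate_expr_vars(row$expr)))))
      if (!v %in% ids)
        add("error", "dangling_reference",
            sprintf("gate %s references undeclared variable %s", g$id, v))
  }

  for (s in kb$sa) {
    for (ref in c(s$disease, s$bx, s$gate))
      if (!ref %in% ids) {
        add("error", "dangling_reference",
            sprintf("sa record for %s references undeclared variable %s",
                    s$disease, ref))
      }
    if (all(c(s$disease, s$bx, s$gate) %in% ids)) {
      if (kinds[s$disease] != "B" || kinds[s$bx] != "BX" || kinds[s$gate] != "SG")
        add("error", "sa_kinds",
            sprintf("sa record for %s must wire B -> SG -> BX kinds", s$disease))
      g <- kb$gates[[s$gate]]
      if (!is.null(g)) {
        if (g$remnant + 1L > length(s$factors) ||
            abs(s$factors[g$remnant + 1L] - 1) > 1e-12)
          add("error", "sa_remnant_factor",
              sprintf("sa record for %s: factor for remnant gate state %d must be 1",
                      s$disease, g$remnant))
      }
    }
  }

  has_errors <- any(vapply(findings, function(f) f$level == "error", logical(1)))
  if (!has_errors) {
    graph <- kb_graph(kb)
    if (!igraph::is_dag(graph)) {
      add("error", "cycle", "the causal graph contains a directed cycle")
    } else {
      # conditional-probability overflow, separable maximization per child
      children <- unique(vapply(kb$links, function(l) l$child, character(1)))
      for (child in children) {
        lks <- links_to(kb, child)
        r_total <- sum(vapply(lks, function(l) l$r, numeric(1)))
        worst <- sum(vapply(lks, function(l)
          (l$r / r_total) * max(colSums(l$strength)), numeric(1)))
        if (worst > 1 + 1e-9)
          add("error", "cpt_overflow",
              sprintf(paste0("variable %s: abnormal mass can reach %.4f > 1 ",
                             "for some joint parent assignment"),
                      child, worst))
      }
      # reachability warnings
      roots <- vapply(disease_ids(kb), function(d) disease_root_var(kb, d),
                      character(1))
      covered <- unique(c(roots,
                          unlist(lapply(roots, reachable_from, kb = kb,
                                        graph = graph))))
      support <- c(disease_ids(kb), risk_factor_ids(kb),
                   ids[kinds %in% c("SG", "C", "D")],
                   unlist(lapply(ids[kinds == "D"], reachable_from, kb = kb,
                                 graph = graph)))
      for (orphan in setdiff(ids, union(covered, support)))
        add("warning", "unreachable_variable",
            sprintf("variable %s is not reachable from any disease root", orphan))
      for (d in disease_ids(kb))
        if (length(reachable_from(kb, disease_root_var(kb, d), graph)) == 0L)
          add("warning", "no_manifestations",
              sprintf("disease %s has no manifestations", d))
    }
  }
  findings
}

validation_errors <- function(findings) {
  vapply(findings[vapply(findings, function(f) f$level == "error", logical(1))],
         function(f) f$message, character(1))
}
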