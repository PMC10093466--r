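#' @importFrom stats setNames
NULL

VALID_KINDS <- c("B", "BX", "X", "SX", "SG", "D", "C")

#' Declare a DUCG variable
#'
#' A variable is a named multi-state node. State 0 always denotes the
#' normal/negative state; states >= 1 are abnormal. The kind tag decides the
#' variable's role in inference:
#' \describe{
#'   \item{B}{disease root with a prior distribution over its states;}
#'   \item{BX}{conditional disease root whose prior is derived from the B
#'     prior and the observed risk factors (see [compute_bx_prior()]);}
#'   \item{X}{consequence variable: symptom, sign, test result, or
#'     risk-factor observation;}
#'   \item{SX}{a manifestation that is the clinical gold standard for one
#'     disease;}
#'   \item{SG}{logic gate combining risk-factor states (see [ducg_gate()]);}
#'   \item{D}{default (unspecified) cause, a root with a prior;}
#'   \item{C}{inert classifier used only to group manifestations.}
#' }
#'
#' @param id Unique token: kind letter(s) followed by an integer index,
#'   e.g. `"B23"`, `"X74"`, `"SX160"`.
#' @param kind One of `"B"`, `"BX"`, `"X"`, `"SX"`, `"SG"`, `"D"`, `"C"`.
#' @param n_states Number of states (>= 2); ignored for kind `"C"`.
#' @param label Human-readable description.
#' @param prior Probability vector over states, required iff kind is `"B"`
#'   or `"D"`, forbidden otherwise.
#' @return An object of class `ducg_variable`.
#' @examples
#' ducg_variable("B23", "B", prior = c(0.97, 0.03),
#'               label = "Laryngopharyngeal reflux")
#' @export
ducg_variable <- function(id, kind, n_states = 2L, label = "", prior = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (identical(kind, "RG"))
    stop("variable '", id, "': RG-type variables are not supported by this ",
         "engine", call. = FALSE)
  kind <- match.arg(kind, VALID_KINDS)
  n_states <- as.integer(n_states)
  if (kind != "C" && n_states < 2L)
    stop("variable '", id, "': n_states must be >= 2", call. = FALSE)
  if (kind %in% c("B", "D")) {
    if (is.null(prior))
      stop("variable '", id, "' of kind ", kind, " requires a prior", call. = FALSE)
    prior <- as.numeric(prior)
    if (length(prior) != n_states)
      stop("variable '", id, "': prior length != n_states", call. = FALSE)
    if (abs(sum(prior) - 1) > 1e-12)
      stop("variable '", id, "': prior must sum to 1", call. = FALSE)
    if (any(prior < 0))
      stop("variable '", id, "': prior has negative mass", call. = FALSE)
  } else if (!is.null(prior)) {
    stop("variable '", id, "' of kind ", kind, " must not carry a prior",
         call. = FALSE)
  }
  structure(list(id = id, kind = kind, n_states = n_states,
                 label = label, prior = prior),
            class = "ducg_variable")
}

#' Declare a weighted causal link
#'
#' A directed causal link from a parent variable to a child, carrying the
#' weighted functional-event parameters: a per-parent causal intensity
#' `r` and a strength matrix `a[k, j]` giving the probability that the
#' causal mechanism, once selected, puts the child into abnormal state
#' `k >= 1` when the parent is in state `j`. The effective contribution of
#' the parent to `Pr(child = k)` is `(r_i / sum(r)) * a[k, j]`, where the
#' sum runs over the child's current parents.
#'
#' @param child,parent Variable ids.
#' @param r Positive causal intensity of this parent.
#' @param strength Numeric matrix with one row per abnormal child state
#'   (state 1 .. n_child_states - 1) and one column per parent state
#'   (state 0 first). Entries in \[0, 1\]. Column 1 (parent normal) is
#'   conventionally all zero: normal states cause nothing unless
#'   explicitly authored.
#' @return An object of class `ducg_link`.
#' @examples
#' # one abnormal child state, binary parent: no effect when parent normal,
#' # probability 0.8 when parent abnormal
#' ducg_link("X21", "BX23", r = 1, strength = matrix(c(0, 0.8), 1))
#' @export
ducg_link <- function(child, parent, r = 1, strength) {
  stopifnot(is.character(child), is.character(parent))
  r <- as.numeric(r)
  if (length(r) != 1L || !is.finite(r) || r <= 0)
    stop("link ", parent, " -> ", child, ": r must be a positive scalar",
         call. = FALSE)
  strength <- as.matrix(strength)
  if (any(!is.finite(strength)) || any(strength < 0) || any(strength > 1))
    stop("link ", parent, " -> ", child,
         ": strength entries must lie in [0, 1]", call. = FALSE)
  structure(list(child = child, parent = parent, r = r,
                 strength = unname(strength)),
            class = "ducg_link")
}

#' Declare a risk-factor logic gate
#'
#' A logic gate (kind `SG`) maps combinations of risk-factor states to gate
#' states through an ordered logic specification table. Each row pairs a
#' gate state with a boolean expression over parent-state literals of the
#' form `X74=1`, combined with `&`, `|`, `!` and parentheses. Evaluation is
#' deterministic: the first row whose expression is true wins; when no row
#' matches, the remnant state holds.
#'
#' @param id Gate variable id (kind `SG`).
#' @param rows List of `list(state = <int>, expr = <string>)` entries, in
#'   priority order.
#' @param remnant Gate state assigned when no row matches (default 0).
#' @return An object of class `ducg_gate`.
#' @examples
#' ducg_gate("SG23", rows = list(list(state = 1L, expr = "X74=1")))
#' @export
ducg_gate <- function(id, rows, remnant = 0L) {
  stopifnot(is.character(id), is.list(rows))
  rows <- lapply(rows, function(row) {
    stopifnot(!is.null(row$state), !is.null(row$expr))
    list(state = as.integer(row$state), expr = as.character(row$expr))
  })
  for (row in rows) parse_gate_expr(row$expr)  # fail fast on bad syntax
  structure(list(id = id, rows = rows, remnant = as.integer(remnant)),
            class = "ducg_gate")
}

#' Declare a risk-factor strength record
#'
#' Records how each state of a logic gate rescales a disease prior: the
#' conditional root `bx` takes abnormal mass `factor[gate state] * Pr(B
#' abnormal)`. The factor for the remnant (risk absent) state must be 1, so
#' an absent risk factor leaves the prior unchanged.
#'
#' @param disease Disease root id (kind `B`).
#' @param bx Conditional root id (kind `BX`).
#' @param gate Gate id (kind `SG`).
#' @param factors Non-negative multipliers indexed by gate state
#'   (state 0 first).
#' @return An object of class `ducg_sa`.
#' @examples
#' ducg_sa("B23", "BX23", "SG23", factors = c(1, 10))
#' @export
ducg_sa <- function(disease, bx, gate, factors) {
  factors <- as.numeric(factors)
  if (any(!is.finite(factors)) || any(factors < 0))
    stop("sa record for ", disease, ": factors must be non-negative",
         call. = FALSE)
  structure(list(disease = disease, bx = bx, gate = gate, factors = factors),
            class = "ducg_sa")
}

#' Assemble a DUCG knowledge base
#'
#' Builds a knowledge-base object from variables, links, gates and
#' risk-factor records. A sub-DUCG (`sub = TRUE`) models one disease as an
#' independent module and must contain exactly one disease root; a complete
#' DUCG is the merge of such modules (see [merge_subgraphs()]).
#'
#' @param variables List of [ducg_variable()] objects.
#' @param links List of [ducg_link()] objects.
#' @param gates List of [ducg_gate()] objects.
#' @param sa List of [ducg_sa()] objects.
#' @param name Knowledge-base name.
#' @param sub Logical: is this a single-disease sub-DUCG?
#' @param provenance Optional named character vector mapping variable ids to
#'   the name of the sub-DUCG that contributed them.
#' @param check Run [validate_kb()] and stop on errors (default `TRUE`).
#' @return An object of class `ducg` (and `ducg_sub` when `sub = TRUE`).
#' @export
ducg_kb <- function(variables, links = list(), gates = list(), sa = list(),
                    name = "kb", sub = FALSE, provenance = NULL,
                    check = TRUE) {
  stopifnot(is.list(variables))
  if (length(variables) == 0L)
    stop("a knowledge base must declare at least one variable", call. = FALSE)
  ids <- vapply(variables, function(v) v$id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate variable ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  variables <- setNames(variables, ids)[order_ids(ids)]
  links <- links[order(vapply(links, function(l) l$child, character(1)),
                       vapply(links, function(l) l$parent, character(1)))]
  gate_ids <- vapply(gates, function(g) g$id, character(1))
  gates <- setNames(gates, gate_ids)[order_ids(gate_ids)]
  sa_ids <- vapply(sa, function(s) s$disease, character(1))
  sa <- setNames(sa, sa_ids)[order_ids(sa_ids)]
  if (is.null(provenance))
    provenance <- setNames(rep(name, length(variables)), names(variables))
  kb <- structure(list(name = name, variables = variables, links = links,
                       gates = gates, sa = sa, provenance = provenance),
                  class = if (sub) c("ducg_sub", "ducg") else "ducg")
  if (check) {
    findings <- validate_kb(kb)
    errs <- findings[vapply(findings, function(f) f$level == "error", logical(1))]
    if (length(errs) > 0L)
      stop("invalid knowledge base '", name, "':\n  ",
           paste(vapply(errs, function(f) f$message, character(1)),
                 collapse = "\n  "),
           call. = FALSE)
  }
  kb
}

#' @export
print.ducg <- function(x, ...) {
  kinds <- vapply(x$variables, function(v) v$kind, character(1))
  cat(if (inherits(x, "ducg_sub")) "<sub-DUCG '" else "<DUCG '", x$name,
      "': ", length(x$variables), " variables (",
      paste(names(table(kinds)), as.integer(table(kinds)),
            sep = ":", collapse = " "),
      "), ", length(x$links), " links, ", length(x$gates), " gates>\n",
      sep = "")
  invisible(x)
}

# ---- internal accessors ----------------------------------------------------

numeric_index <- function(id) {
  as.integer(sub("^[A-Za-z]+", "", id))
}

# canonical id ordering: by kind letter(s), then numeric index
order_ids <- function(ids) {
  order(sub("[0-9]+$", "", ids), numeric_index(ids))
}

var_kind <- function(kb, id) kb$variables[[id]]$kind

disease_ids <- function(kb) {
  ids <- names(kb$variables)
  ids[vapply(kb$variables, function(v) v$kind == "B", logical(1))]
}

# the variable from which a disease's manifestations hang: its BX when a
# risk-factor triple exists, else the B root itself
disease_root_var <- function(kb, disease) {
  if (!is.null(kb$sa[[disease]])) kb$sa[[disease]]$bx else disease
}

links_to <- function(kb, child) {
  kb$links[vapply(kb$links, function(l) l$child == child, logical(1))]
}

parent_ids <- function(kb, child) {
  vapply(links_to(kb, child), function(l) l$parent, character(1))
}

# risk-factor variables: parents of any logic gate (anamnesis items consumed
# by gate logic, not evidence the causal net has to explain)
risk_factor_ids <- function(kb) {
  unique(unlist(lapply(kb$gates, function(g)
    unlist(lapply(g$rows, function(row) gate_expr_vars(row$expr))))))
}

# edge list of the causal graph: links, plus gate wiring
# (risk factor -> SG, SG -> BX, B -> BX)
kb_edges <- function(kb) {
  from <- vapply(kb$links, function(l) l$parent, character(1))
  to <- vapply(kb$links, function(l) l$child, character(1))
  for (g in kb$gates) {
    vars <- unique(unlist(lapply(g$rows, function(row) gate_expr_vars(row$expr))))
    from <- c(from, vars)
    to <- c(to, rep(g$id, length(vars)))
  }
  for (s in kb$sa) {
    from <- c(from, s$gate, s$disease)
    to <- c(to, s$bx, s$bx)
  }
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}

kb_graph <- function(kb) {
  igraph::graph_from_data_frame(kb_edges(kb), directed = TRUE,
                                vertices = names(kb$variables))
}

# ids reachable from `from` by directed edges (excluding `from` itself)
reachable_from <- function(kb, from, graph = kb_graph(kb)) {
  if (!from %in% names(kb$variables)) return(character(0))
  out <- igraph::subcomponent(graph, from, mode = "out")
  setdiff(names(out), from)
}
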