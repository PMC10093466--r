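# Symbolic chain expansion into sum-of-products.
#
# A consequence event X_{n,k} is expanded along the reverse causal
# direction: X_{n,k} = sum_i sum_j (r_i / r) A_{nk;ij} V_{ij}, recursively,
# until only root events (B/BX/D) and functional events (A) remain. The
# result is a symbolic sum of product terms, each carrying a rational
# weight factor accumulated from the r-ratios.
#
# Atomic event tokens: root-state events "B23=1"; functional events
# "A[X21,1|BX23,1]" (child id and state | parent id and state).

sop <- function(terms) structure(list(terms = terms), class = "ducg_sop")

sop_term <- function(weight, events) {
  list(weight = weight, events = sort(unique(events)))
}

root_event <- function(var, state) paste0(var, "=", state)

functional_event <- function(child, k, parent, j)
  sprintf("A[%s,%d|%s,%d]", child, k, parent, j)

is_root_event <- function(event) grepl("^[A-Za-z]+[0-9]+=[0-9]+$", event)

# drop terms containing two different states of the same root variable,
# and collapse duplicate terms by summing weights
sop_normalize <- function(x) {
  kept <- list()
  for (term in x$terms) {
    roots <- term$events[is_root_event(term$events)]
    vars <- sub("=.*$", "", roots)
    if (anyDuplicated(vars)) next  # state exclusion: the term is zero
    key <- paste(term$events, collapse = " ")
    if (is.null(kept[[key]])) kept[[key]] <- term
    else kept[[key]]$weight <- kept[[key]]$weight + term$weight
  }
  sop(unname(kept))
}

sop_add <- function(a, b) sop_normalize(sop(c(a$terms, b$terms)))

# product of two sums of products; duplicate atomic events within a term
# are absorbed to a single occurrence (AA = A)
sop_multiply <- function(a, b) {
  terms <- list()
  for (ta in a$terms) for (tb in b$terms)
    terms[[length(terms) + 1L]] <- sop_term(ta$weight * tb$weight,
                                            c(ta$events, tb$events))
  sop_normalize(sop(terms))
}

sop_scale <- function(x, factor) {
  sop(lapply(x$terms, function(t) sop_term(t$weight * factor, t$events)))
}

#' @export
print.ducg_sop <- function(x, ...) {
  if (length(x$terms) == 0L) {
    cat("0\n")
    return(invisible(x))
  }
  cat(paste(vapply(x$terms, function(t) {
    w <- if (abs(t$weight - 1) < 1e-12) "" else paste0(format(t$weight), " ")
    paste0(w, paste(t$events, collapse = " "))
  }, character(1)), collapse = " + "), "\n")
  invisible(x)
}

#' Expand an event into a sum of products of root and functional events
#'
#' Performs the symbolic reverse-chain expansion: a consequence event is
#' substituted by the r-weighted sum over its causal parents of the
#' functional event times the parent event, recursively until only root
#' events remain. State exclusion (a term naming two states of one root is
#' zero) and absorption (a repeated atomic event counts once) are applied
#' throughout. Parent states whose strength entry is zero contribute
#' nothing and are omitted.
#'
#' Expanding a normal-state event (state 0) returns a complement object
#' representing one minus the sum of the variable's abnormal-state
#' expansions.
#'
#' @param kb A `ducg` (or a `ducg_view`, whose graph is used).
#' @param var Variable id of the event.
#' @param state Observed state of the event.
#' @return A `ducg_sop` (state >= 1) or `ducg_sop_complement` (state 0).
#' @examples
#' kb <- ducg_kb(list(
#'   ducg_variable("B1", "B", prior = c(0.9, 0.1)),
#'   ducg_variable("X2", "X"), ducg_variable("X3", "X")),
#'   list(ducg_link("X2", "B1", strength = matrix(c(0, 0.8), 1)),
#'        ducg_link("X3", "X2", strength = matrix(c(0, 0.5), 1))))
#' expand(kb, "X3", 1)  # A[X3,1|X2,1] A[X2,1|B1,1] B1=1
#' @export
expand <- function(kb, var, state) {
  if (inherits(kb, "ducg_view")) kb <- kb$kb
  v <- kb$variables[[var]]
  if (is.null(v)) stop("unknown variable ", var, call. = FALSE)
  state <- as.integer(state)
  if (v$kind %in% c("B", "BX", "D"))
    return(sop(list(sop_term(1, root_event(var, state)))))
  if (state == 0L) {
    abnormal <- lapply(seq_len(v$n_states - 1L), function(k)
      expand_abnormal(kb, var, k, active = character(0)))
    return(structure(list(var = var, abnormal = abnormal),
                     class = "ducg_sop_complement"))
  }
  expand_abnormal(kb, var, state, active = character(0))
}

expand_abnormal <- function(kb, var, state, active) {
  if (var %in% active)
    stop("cycle encountered while expanding ", var, call. = FALSE)
  v <- kb$variables[[var]]
  if (v$kind %in% c("B", "BX", "D"))
    return(sop(list(sop_term(1, root_event(var, state)))))
  lks <- links_to(kb, var)
  if (length(lks) == 0L) return(sop(list()))  # no cause: the event is void
  r_total <- sum(vapply(lks, function(l) l$r, numeric(1)))
  total <- sop(list())
  for (l in lks) {
    for (j in seq_len(ncol(l$strength)) - 1L) {
      if (l$strength[state, j + 1L] == 0) next
      parent_sop <- expand_abnormal(kb, l$parent, j, c(active, var))
      piece <- sop_multiply(
        sop(list(sop_term(l$r / r_total,
                          functional_event(var, state, l$parent, j)))),
        parent_sop)
      total <- sop_add(total, piece)
    }
  }
  total
}

#' Numeric value of a sum of products
#'
#' Evaluates a symbolic expansion by substituting each root event with its
#' prior mass and each functional event with its strength entry, treating
#' distinct atomic events as independent. This reproduces the joint
#' probability on single-path causal chains; on graphs where a root feeds
#' the evidence through several converging paths the engine's exact
#' evaluation ([evaluate()]) is authoritative.
#'
#' @param x A `ducg_sop`.
#' @param kb The knowledge base providing priors and strengths.
#' @param priors Optional named list overriding root priors (e.g.
#'   risk-adjusted BX priors); names are variable ids, values probability
#'   vectors (normal state first).
#' @return A scalar probability.
#' @export
sop_probability <- function(x, kb, priors = list()) {
  if (inherits(kb, "ducg_view")) kb <- kb$kb
  event_prob <- function(event) {
    if (is_root_event(event)) {
      var <- sub("=.*$", "", event)
      state <- as.integer(sub("^.*=", "", event))
      pr <- priors[[var]] %||% kb$variables[[var]]$prior
      if (is.null(pr)) stop("no prior for root ", var, call. = FALSE)
      return(unname(pr[state + 1L]))
    }
    m <- regmatches(event,
                    regexec("^A\\[([^,]+),([0-9]+)\\|([^,]+),([0-9]+)\\]$",
                            event))[[1]]
    link <- Filter(function(l) l$child == m[2] && l$parent == m[4], kb$links)
    if (length(link) == 0L) stop("no link behind ", event, call. = FALSE)
    link[[1]]$strength[as.integer(m[3]), as.integer(m[5]) + 1L]
  }
  sum(vapply(x$terms, function(t)
    t$weight * prod(vapply(t$events, event_prob, numeric(1))), numeric(1)))
}
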