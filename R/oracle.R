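# Brute-force exact probability computation on small graphs.
#
# The oracle makes the mixture semantics of the weighted functional events
# explicit: for every consequence variable it enumerates the per-child
# parent-selection variable (parent i chosen with probability r_i / r) and
# the outcome of the selected causal mechanism (child state k with
# probability a[k, j] given the parent's state j, residual mass on the
# normal state), together with the states of every default-cause root.
# Every complete world is visited exactly once; the probabilities of the
# worlds consistent with the hypothesis and the evidence are summed. It is
# deliberately naive and exponential, and refuses graphs above a size cap.

#' Count the atomic events of a knowledge base
#'
#' Atomic events are the root states (over B, BX and D variables) plus the
#' functional events (one per causal link). This is the size measure used
#' by the oracle's enumeration cap.
#'
#' @param kb A `ducg` or `ducg_view`.
#' @return Integer count.
#' @export
count_atomic_events <- function(kb) {
  if (inherits(kb, "ducg_view")) kb <- kb$kb
  roots <- kb$variables[vapply(kb$variables, function(v)
    v$kind %in% c("B", "BX", "D"), logical(1))]
  sum(vapply(roots, function(v) v$n_states, integer(1))) + length(kb$links)
}

#' Exact joint probability by exhaustive enumeration
#'
#' Ground-truth counterpart of [evaluate()]: computes
#' `zeta = Pr(hypothesis, evidence)` on a single-fault view by enumerating
#' every complete world at the causal-mechanism level (parent selectors
#' and mechanism outcomes, not pre-marginalized state distributions) and
#' summing the consistent ones. Shares the engine's conventions for
#' risk-factor-adjusted priors, fixed-normal other diseases, the
#' normal-state residual, and the isolated-evidence leak factor, but none
#' of its computational shortcuts.
#'
#' @param view A `ducg_view` (from [decompose()] or built directly).
#' @param ev Evidence; defaults to the view's stored evidence.
#' @param leak Isolated-evidence leak probability.
#' @param cap Refuse enumeration when [count_atomic_events()] exceeds this
#'   (default 20); memory and time grow exponentially.
#' @return The scalar joint probability.
#' @export
enumerate_zeta <- function(view, ev = view$evidence, leak = 0.01, cap = 20L) {
  stopifnot(inherits(view, "ducg_view"))
  if (!inherits(ev, "ducg_evidence")) ev <- ducg_evidence(ev)
  kb <- view$kb
  n_atomic <- count_atomic_events(kb)
  if (n_atomic > cap)
    stop("refusing enumeration: ", n_atomic, " atomic events exceed cap ",
         cap, call. = FALSE)

  sp <- split_risk_evidence(kb, ev)
  obs <- sp$net$observations
  obs <- obs[names(obs) %in% names(kb$variables)]
  prior <- compute_bx_prior(kb, view$disease, sp$risk)
  p_h <- unname(prior[as.character(view$state)])
  if (p_h == 0) return(0)

  cls <- classify_abnormal(view, names(obs[obs != 0L]))
  live_obs <- obs[setdiff(names(obs), cls$isolated)]

  clamped <- setNames(integer(0), character(0))
  clamped[view$root] <- view$state
  for (d in setdiff(disease_ids(kb), view$disease)) {
    clamped[d] <- 0L
    clamped[disease_root_var(kb, d)] <- 0L
  }
  rf <- intersect(risk_factor_ids(kb), names(kb$variables))
  clamped[setdiff(rf, names(sp$risk))] <- 0L
  for (id in intersect(rf, names(sp$risk))) clamped[id] <- sp$risk[[id]]
  live_obs <- live_obs[setdiff(names(live_obs), names(clamped))]

  graph <- links_graph(kb)
  topo <- names(igraph::topo_sort(graph, mode = "out"))
  process <- setdiff(topo, names(clamped))
  process <- process[vapply(process, function(v)
    kb$variables[[v]]$kind %in% c("X", "SX", "D"), logical(1))]

  total <- 0
  recurse <- function(pos, states, prob) {
    if (prob == 0) return()
    if (pos > length(process)) {
      ok <- all(vapply(names(live_obs), function(v)
        states[[v]] == live_obs[[v]], logical(1)))
      if (ok) total <<- total + prob
      return()
    }
    v <- process[pos]
    var <- kb$variables[[v]]
    if (var$kind == "D") {
      for (s in seq_len(var$n_states) - 1L) {
        states[v] <- s
        recurse(pos + 1L, states, prob * var$prior[s + 1L])
      }
      return()
    }
    lks <- links_to(kb, v)
    if (length(lks) == 0L) {  # no cause present: deterministically normal
      states[v] <- 0L
      recurse(pos + 1L, states, prob)
      return()
    }
    r_total <- sum(vapply(lks, function(l) l$r, numeric(1)))
    for (l in lks) {  # parent-selection variable
      p_sel <- l$r / r_total
      j <- states[[l$parent]]
      a_col <- l$strength[, j + 1L]
      for (k in seq_len(var$n_states - 1L)) {  # mechanism fires state k
        states[v] <- k
        recurse(pos + 1L, states, prob * p_sel * a_col[k])
      }
      states[v] <- 0L  # mechanism produces nothing
      recurse(pos + 1L, states, prob * p_sel * max(0, 1 - sum(a_col)))
    }
  }
  recurse(1L, clamped, 1)
  p_h * leak^length(cls$isolated) * total
}
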