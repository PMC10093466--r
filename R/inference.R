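# The chain-reasoning algorithm: evidence-driven graph simplification,
# single-fault decomposition into per-hypothesis views, likelihood
# evaluation under the weighted functional-event semantics, and posterior
# computation.

# links-only causal graph (gate wiring excluded: gates act on priors, not
# on the evidence likelihood)
links_graph <- function(kb) {
  edges <- data.frame(
    from = vapply(kb$links, function(l) l$parent, character(1)),
    to = vapply(kb$links, function(l) l$child, character(1)),
    stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = TRUE,
                                vertices = names(kb$variables))
}

links_reachable <- function(graph, from) {
  if (!from %in% igraph::V(graph)$name) return(character(0))
  setdiff(names(igraph::subcomponent(graph, from, mode = "out")), from)
}

# Pr(child state | joint parent states), the weighted mixture of Eq-style
# functional events: abnormal state k gets sum_i (r_i/r) a_i[k, j_i];
# state 0 takes the residual mass. A parentless variable is deterministically
# normal.
child_dist <- function(kb, child, parent_states) {
  v <- kb$variables[[child]]
  lks <- links_to(kb, child)
  if (length(lks) == 0L) return(c(1, rep(0, v$n_states - 1L)))
  r_total <- sum(vapply(lks, function(l) l$r, numeric(1)))
  abnormal <- rep(0, v$n_states - 1L)
  for (l in lks) {
    j <- parent_states[[l$parent]]
    abnormal <- abnormal + (l$r / r_total) * l$strength[, j + 1L]
  }
  c(max(0, 1 - sum(abnormal)), abnormal)
}

restrict_kb <- function(kb, keep) {
  keep <- intersect(names(kb$variables), keep)
  ducg_kb(
    unname(kb$variables[keep]),
    kb$links[vapply(kb$links, function(l)
      l$child %in% keep && l$parent %in% keep, logical(1))],
    unname(kb$gates[vapply(kb$gates, function(g) g$id %in% keep, logical(1))]),
    unname(kb$sa[vapply(kb$sa, function(s)
      all(c(s$disease, s$bx, s$gate) %in% keep), logical(1))]),
    name = kb$name,
    provenance = kb$provenance[keep],
    check = FALSE)
}

#' Simplify a knowledge base under the current evidence
#'
#' First step of chain reasoning: removes variables and causalities that
#' are irrelevant under the observed case, so the remaining graph shows
#' only the causalities between the evidence and its candidate root
#' causes. Three rules are applied to a fixpoint:
#' \describe{
#'   \item{R1 (barren removal)}{unobserved non-root variables with no
#'     observed descendant are dropped;}
#'   \item{R2 (unsupported hypotheses)}{disease roots with no directed
#'     path to any abnormal evidence variable are dropped, together with
#'     their gate machinery;}
#'   \item{R3 (deterministic contradiction)}{when a parent state implies
#'     an abnormal child state with certainty but the child is observed
#'     normal, that parent state is marked unviable; a disease all of
#'     whose abnormal states are unviable is dropped.}
#' }
#' Per-parent weights are implicitly renormalized over surviving parents,
#' because the mixture weight of a parent is its intensity divided by the
#' sum of intensities of the child's current parents.
#'
#' @param kb A `ducg` knowledge base.
#' @param ev A [ducg_evidence()] object (or named state vector).
#' @return The reduced `ducg`, carrying attributes `risk` (risk-factor
#'   observations), `unviable` (parent states eliminated by R3) and
#'   `no_abnormal` (flag set when E' is empty so only priors remain
#'   informative).
#' @export
simplify <- function(kb, ev) {
  if (!inherits(ev, "ducg_evidence"))
    ev <- ducg_evidence(ev, kb = kb)
  else ev <- ducg_evidence(ev$observations, kb = kb)  # re-validate
  sp <- split_risk_evidence(kb, ev)
  abnormal <- names(sp$net$abnormal)
  observed <- names(sp$net$observations)
  graph <- links_graph(kb)

  diseases <- disease_ids(kb)
  if (length(abnormal) > 0L) {
    diseases <- diseases[vapply(diseases, function(d)
      any(abnormal %in% links_reachable(graph, disease_root_var(kb, d))),
      logical(1))]
  }

  unviable <- list()
  repeat {
    # R1 + R2: keep observed vars, their ancestors, surviving disease
    # machinery, and default causes that can reach an observation
    keep_roots <- unlist(lapply(diseases, function(d) {
      s <- kb$sa[[d]]
      if (is.null(s)) d else c(d, s$bx, s$gate,
                               unlist(lapply(kb$gates[[s$gate]]$rows,
                                             function(row) gate_expr_vars(row$expr))))
    }))
    d_roots <- names(kb$variables)[vapply(kb$variables, function(v)
      v$kind == "D", logical(1))]
    d_roots <- d_roots[vapply(d_roots, function(d)
      any(observed %in% links_reachable(graph, d)), logical(1))]
    ancestors <- unique(unlist(lapply(observed, function(o)
      names(igraph::subcomponent(graph, o, mode = "in")))))
    keep <- unique(c(observed, names(sp$risk), ancestors, keep_roots, d_roots))
    # ancestors may include roots of dropped diseases; prune those
    dropped_roots <- unlist(lapply(setdiff(disease_ids(kb), diseases),
                                   function(d) c(d, disease_root_var(kb, d))))
    keep <- setdiff(keep, dropped_roots)
    reduced <- restrict_kb(kb, keep)

    # R3 on the reduced graph
    changed <- FALSE
    for (child in names(sp$net$normal)) {
      lks <- links_to(reduced, child)
      if (length(lks) == 0L) next
      r_total <- sum(vapply(lks, function(l) l$r, numeric(1)))
      for (l in lks) {
        share <- l$r / r_total
        for (j in seq_len(ncol(l$strength) - 1L)) {  # abnormal parent states
          if (any(share * l$strength[, j + 1L] >= 1 - 1e-12)) {
            key <- paste0(l$parent, "=", j)
            if (is.null(unviable[[key]])) {
              unviable[[key]] <- c(var = l$parent, state = j)
              changed <- TRUE
            }
          }
        }
      }
    }
    if (changed) {
      # diseases whose root has no viable abnormal state left are dropped
      dead <- vapply(diseases, function(d) {
        root <- disease_root_var(kb, d)
        nst <- kb$variables[[d]]$n_states
        all(paste0(root, "=", seq_len(nst - 1L)) %in% names(unviable))
      }, logical(1))
      if (any(dead)) {
        diseases <- diseases[!dead]
        next
      }
    }
    break
  }

  structure(reduced,
            class = class(kb),
            risk = sp$risk,
            unviable = unname(unviable),
            no_abnormal = length(abnormal) == 0L)
}

#' Decompose a simplified graph into single-fault hypothesis views
#'
#' Second step of chain reasoning, under the single-fault premise that all
#' abnormal evidence stems from one root cause at a time: for every
#' abnormal state of every surviving disease root, a view is produced in
#' which that hypothesis holds and every other disease root is fixed to
#' its normal state. Hypothesis states ruled out by simplification rule R3
#' are skipped.
#'
#' @param simplified Output of [simplify()].
#' @param ev The case evidence (kept for downstream evaluation).
#' @return List of `ducg_view` objects in deterministic order (ascending
#'   disease index, then state); empty, with a `message` attribute, when
#'   no disease root survives.
#' @export
decompose <- function(simplified, ev) {
  if (!inherits(ev, "ducg_evidence")) ev <- ducg_evidence(ev)
  diseases <- disease_ids(simplified)
  unviable <- vapply(attr(simplified, "unviable") %||% list(),
                     function(u) paste0(u[["var"]], "=", u[["state"]]),
                     character(1))
  views <- list()
  for (d in diseases[order(numeric_index(diseases))]) {
    root <- disease_root_var(simplified, d)
    for (s in seq_len(simplified$variables[[d]]$n_states - 1L)) {
      if (paste0(root, "=", s) %in% unviable) next
      views[[length(views) + 1L]] <- structure(
        list(kb = simplified, disease = d, state = s, root = root,
             evidence = ev),
        class = "ducg_view")
    }
  }
  if (length(views) == 0L)
    attr(views, "message") <- "no surviving disease root can explain the evidence"
  views
}

# classify abnormal evidence for one view: explained (causal path from the
# hypothesis root or a default cause) vs isolated (no such path)
classify_abnormal <- function(view, net_abnormal) {
  kb <- view$kb
  graph <- links_graph(kb)
  sources <- c(view$root,
               names(kb$variables)[vapply(kb$variables, function(v)
                 v$kind == "D", logical(1))])
  reach <- unique(unlist(lapply(sources, links_reachable, graph = graph)))
  list(explained = intersect(net_abnormal, reach),
       isolated = setdiff(net_abnormal, reach))
}

#' Joint probability of a hypothesis and the evidence
#'
#' Computes `zeta = Pr(hypothesis, evidence)` on one single-fault view
#' under the generative semantics of the weighted functional events: the
#' hypothesis root takes its risk-factor-adjusted prior mass, every other
#' disease root is fixed normal, each consequence variable's state
#' distribution given its parents is the r-weighted mixture of strength
#' columns with residual mass on the normal state, and unobserved
#' intermediate variables are marginalized exactly. Abnormal evidence with
#' no causal path from the hypothesis (isolated evidence) contributes the
#' factor `leak` per observation; normal evidence contributes its residual
#' normal-state mass, acting as negative evidence.
#'
#' @param view A `ducg_view` from [decompose()].
#' @param ev Evidence; defaults to the evidence stored in the view.
#' @param leak Probability in \[0, 1) charged per isolated abnormal
#'   observation.
#' @return The scalar joint probability.
#' @export
evaluate <- function(view, ev = view$evidence, leak = 0.01) {
  stopifnot(inherits(view, "ducg_view"), leak >= 0, leak < 1)
  if (!inherits(ev, "ducg_evidence")) ev <- ducg_evidence(ev)
  kb <- view$kb
  sp <- split_risk_evidence(kb, ev)
  obs <- sp$net$observations
  obs <- obs[names(obs) %in% names(kb$variables)]

  prior <- compute_bx_prior(kb, view$disease, sp$risk)
  p <- unname(prior[as.character(view$state)])
  if (p == 0) return(0)

  cls <- classify_abnormal(view, names(obs[obs != 0L]))
  p <- p * leak^length(cls$isolated)
  live_obs <- obs[setdiff(names(obs), cls$isolated)]

  # clamped context: hypothesis root at its state, all other disease root
  # variables normal, risk factors at their observed-or-absent state
  clamped <- setNames(rep(0L, 0), character(0))
  clamped[view$root] <- view$state
  for (d in setdiff(disease_ids(kb), view$disease)) {
    clamped[d] <- 0L
    clamped[disease_root_var(kb, d)] <- 0L
  }
  rf <- intersect(risk_factor_ids(kb), names(kb$variables))
  clamped[setdiff(rf, names(sp$risk))] <- 0L
  clamped[intersect(rf, names(sp$risk))] <- sp$risk[intersect(rf, names(sp$risk))]
  live_obs <- live_obs[setdiff(names(live_obs), names(clamped))]

  graph <- links_graph(kb)
  ancestors <- unique(unlist(lapply(names(live_obs), function(o)
    names(igraph::subcomponent(graph, o, mode = "in")))))
  latent <- setdiff(ancestors, c(names(live_obs), names(clamped)))
  process <- c(names(live_obs), latent)
  if (length(process) == 0L) return(p)
  topo <- names(igraph::topo_sort(graph, mode = "out"))
  process <- topo[topo %in% process]

  sum_worlds <- function(pos, states) {
    if (pos > length(process)) return(1)
    v <- process[pos]
    var <- kb$variables[[v]]
    dist <- if (var$kind == "D") var$prior else {
      ps <- states[parent_ids(kb, v)]
      child_dist(kb, v, as.list(ps))
    }
    if (v %in% names(live_obs)) {
      pr <- dist[live_obs[[v]] + 1L]
      if (pr == 0) return(0)
      states[v] <- live_obs[[v]]
      return(pr * sum_worlds(pos + 1L, states))
    }
    total <- 0
    for (s in seq_len(var$n_states) - 1L) {
      if (dist[s + 1L] == 0) next
      states[v] <- s
      total <- total + dist[s + 1L] * sum_worlds(pos + 1L, states)
    }
    total
  }
  p * sum_worlds(1L, clamped)
}

#' Posterior probabilities from joint probabilities
#'
#' Normalizes the per-hypothesis joint probabilities into posteriors
#' `h = zeta / sum(zeta)` and ranks hypotheses by descending posterior,
#' ties broken by ascending variable index then state.
#'
#' @param zetas Numeric vector of joint probabilities named
#'   `"<disease>,<state>"` (e.g. `"B23,1"`), or a list of views paired
#'   with `zeta` values via `attr`.
#' @return A `ducg_diagnosis` data frame with columns `disease`, `state`,
#'   `zeta`, `posterior`. All-zero input yields an empty ranking flagged
#'   with attribute `no_explanation = TRUE`.
#' @export
posterior <- function(zetas) {
  stopifnot(length(zetas) >= 1L, !is.null(names(zetas)))
  if (any(zetas < 0)) stop("negative joint probability", call. = FALSE)
  parts <- strsplit(names(zetas), ",", fixed = TRUE)
  res <- data.frame(
    disease = vapply(parts, `[`, character(1), 1L),
    state = as.integer(vapply(parts, `[`, character(1), 2L)),
    zeta = as.numeric(zetas),
    stringsAsFactors = FALSE)
  if (all(res$zeta == 0)) {
    out <- res[0, ]
    out$posterior <- numeric(0)
    return(structure(out, class = c("ducg_diagnosis", "data.frame"),
                     no_explanation = TRUE))
  }
  res$posterior <- res$zeta / sum(res$zeta)
  res <- res[order(-res$posterior, numeric_index(res$disease), res$state), ]
  rownames(res) <- NULL
  structure(res, class = c("ducg_diagnosis", "data.frame"),
            no_explanation = FALSE)
}

#' @export
print.ducg_diagnosis <- function(x, digits = 4, ...) {
  if (nrow(x) == 0L) {
    cat("<diagnosis: no hypothesis explains the evidence>\n")
    return(invisible(x))
  }
  df <- data.frame(hypothesis = paste0(x$disease, ",", x$state),
                   label = if (!is.null(x$label)) x$label else "",
                   zeta = signif(x$zeta, digits),
                   posterior = sprintf("%.2f%%", 100 * x$posterior))
  if (!is.null(x$gold_standard))
    df$gold <- ifelse(x$gold_standard, "[gold-standard confirmed]", "")
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Differential diagnosis of a case
#'
#' Runs the full chain-reasoning pipeline: [simplify()] the knowledge base
#' under the evidence, [decompose()] it into single-fault hypothesis
#' views, [evaluate()] the joint probability of each hypothesis with the
#' evidence, and normalize with [posterior()]. The result carries the
#' per-hypothesis evidence interpretation used for graphical explanation,
#' and flags hypotheses confirmed by an observed gold-standard (SX)
#' manifestation.
#'
#' @param kb A `ducg` knowledge base.
#' @param ev A [ducg_evidence()] or named state vector.
#' @param leak Isolated-evidence leak probability (default 0.01).
#' @return A `ducg_diagnosis` data frame (see [posterior()]) with extra
#'   columns `label` and `gold_standard`, and attributes `views`,
#'   `interpretations`, `simplified`, `evidence`.
#' @examples
#' kb <- three_disease_kb()
#' diagnose(kb, c(X21 = 1, X150 = 1, X22 = 0))
#' @export
diagnose <- function(kb, ev, leak = 0.01) {
  if (!inherits(ev, "ducg_evidence")) ev <- ducg_evidence(ev, kb = kb)
  simplified <- simplify(kb, ev)
  views <- decompose(simplified, ev)
  if (length(views) == 0L) {
    res <- posterior(c(none = 0)[0])
    attr(res, "no_explanation") <- TRUE
    attr(res, "evidence") <- ev
    return(res)
  }
  zetas <- vapply(views, evaluate, numeric(1), ev = ev, leak = leak)
  names(zetas) <- vapply(views, function(v)
    paste0(v$disease, ",", v$state), character(1))
  res <- posterior(zetas)
  res$label <- vapply(res$disease, function(d)
    kb$variables[[d]]$label, character(1))

  # gold-standard flag: abnormal SX evidence on a manifestation of d
  graph <- links_graph(simplified)
  sx_obs <- names(ev$abnormal)[vapply(names(ev$abnormal), function(id)
    !is.null(kb$variables[[id]]) && kb$variables[[id]]$kind == "SX",
    logical(1))]
  res$gold_standard <- vapply(res$disease, function(d)
    length(sx_obs) > 0L &&
      any(sx_obs %in% links_reachable(graph, disease_root_var(simplified, d))),
    logical(1))

  attr(res, "views") <- views
  attr(res, "simplified") <- simplified
  attr(res, "evidence") <- ev
  attr(res, "interpretations") <- lapply(views, interpret, ev = ev)
  res
}

#' Rank unobserved findings by one-step value of information
#'
#' Scores every unobserved manifestation by the expected reduction in
#' posterior entropy that observing it would bring: outcome probabilities
#' come from the current posterior mixture, and for each outcome the
#' posterior is re-derived by Bayes' rule from the per-hypothesis
#' conditional probabilities. The returned candidates are sorted by
#' descending expected information gain, ties broken by ascending
#' variable index.
#'
#' @param kb A `ducg` knowledge base.
#' @param ev Current evidence.
#' @param current A `ducg_diagnosis` from [diagnose()]; recomputed when
#'   omitted.
#' @param top_m Number of suggestions to return.
#' @param leak Isolated-evidence leak probability.
#' @param confirm Posterior above which the diagnosis is considered
#'   confirmed and no further question is suggested (default 0.99).
#' @return Data frame with columns `variable`, `label`, `gain`; empty when
#'   the top hypothesis exceeds `confirm` or nothing is unobserved.
#' @export
suggest_next <- function(kb, ev, current = NULL, top_m = 5L, leak = 0.01,
                         confirm = 0.99) {
  if (!inherits(ev, "ducg_evidence")) ev <- ducg_evidence(ev, kb = kb)
  if (is.null(current)) current <- diagnose(kb, ev, leak = leak)
  empty <- data.frame(variable = character(0), label = character(0),
                      gain = numeric(0))
  if (nrow(current) == 0L || max(current$posterior) >= confirm) return(empty)
  post <- current$posterior
  names(post) <- paste0(current$disease, ",", current$state)
  # views over the full graph: candidates must still be present when a
  # hypothetical observation on them is evaluated (the simplified views
  # inside `current` have pruned everything unobserved)
  views <- lapply(seq_len(nrow(current)), function(i)
    structure(list(kb = kb, disease = current$disease[i],
                   state = current$state[i],
                   root = disease_root_var(kb, current$disease[i]),
                   evidence = ev),
              class = "ducg_view"))
  zeta0 <- vapply(views, evaluate, numeric(1), ev = ev, leak = leak)
  names(zeta0) <- names(post)

  kinds <- vapply(kb$variables, function(v) v$kind, character(1))
  candidates <- setdiff(
    names(kb$variables)[kinds %in% c("X", "SX")],
    c(names(ev$observations), risk_factor_ids(kb)))
  candidates <- candidates[order(numeric_index(candidates))]
  if (length(candidates) == 0L) return(empty)

  entropy <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  }
  h0 <- entropy(post)
  gains <- vapply(candidates, function(v) {
    n_states <- kb$variables[[v]]$n_states
    # cond[s, h] = Pr(v = s | h, E), normalized per hypothesis
    cond <- vapply(seq_len(n_states) - 1L, function(s) {
      ev_s <- ducg_evidence(c(ev$observations, setNames(s, v)))
      zeta_s <- vapply(views, evaluate, numeric(1), ev = ev_s, leak = leak)
      names(zeta_s) <- vapply(views, function(w)
        paste0(w$disease, ",", w$state), character(1))
      ifelse(zeta0 > 0, zeta_s[names(post)] / zeta0, 0)
    }, numeric(length(post)))
    cond <- matrix(cond, nrow = length(post))
    norm <- rowSums(cond)
    cond[norm > 0, ] <- cond[norm > 0, , drop = FALSE] / norm[norm > 0]
    expected <- 0
    for (s in seq_len(n_states)) {
      p_s <- sum(post * cond[, s])
      if (p_s <= 0) next
      expected <- expected + p_s * entropy(post * cond[, s] / p_s)
    }
    h0 - expected
  }, numeric(1))

  ord <- order(-gains, numeric_index(candidates))
  out <- data.frame(
    variable = candidates[ord],
    label = vapply(candidates[ord], function(v) kb$variables[[v]]$label,
                   character(1)),
    gain = gains[ord],
    stringsAsFactors = FALSE)
  utils::head(out, top_m)
}
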