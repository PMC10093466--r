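# Tiny knowledge bases assembled in code for unit and property tests.

row1 <- function(...) matrix(c(...), nrow = 1)

# one disease, one manifestation: B1 --a--> X2
one_link_kb <- function(p = 0.1, a = 0.8) {
  ducg_kb(list(ducg_variable("B1", "B", prior = c(1 - p, p)),
               ducg_variable("X2", "X")),
          list(ducg_link("X2", "B1", strength = row1(0, a))),
          name = "one_link")
}

# single-path chain B1 -> X2 -> X3
chain_kb <- function(p = 0.1, a12 = 0.8, a23 = 0.5) {
  ducg_kb(list(ducg_variable("B1", "B", prior = c(1 - p, p)),
               ducg_variable("X2", "X"),
               ducg_variable("X3", "X")),
          list(ducg_link("X2", "B1", strength = row1(0, a12)),
               ducg_link("X3", "X2", strength = row1(0, a23))),
          name = "chain")
}

# two diseases with one shared and one distinguishing manifestation each
two_disease_kb <- function(a_unique = 0.9, a_shared = 0.5,
                           p1 = 0.05, p2 = 0.05) {
  ducg_kb(list(ducg_variable("B1", "B", prior = c(1 - p1, p1)),
               ducg_variable("B2", "B", prior = c(1 - p2, p2)),
               ducg_variable("X10", "X"),   # only B1
               ducg_variable("X11", "X"),   # only B2
               ducg_variable("X12", "X")),  # shared
          list(ducg_link("X10", "B1", strength = row1(0, a_unique)),
               ducg_link("X11", "B2", strength = row1(0, a_unique)),
               ducg_link("X12", "B1", strength = row1(0, a_shared)),
               ducg_link("X12", "B2", strength = row1(0, a_shared))),
          name = "two_disease")
}

# grab the decomposed view for one hypothesis
view_for <- function(kb, ev, disease, state = 1L) {
  if (!inherits(ev, "ducg_evidence")) ev <- ducg_evidence(ev, kb = kb)
  views <- decompose(simplify(kb, ev), ev)
  for (v in views) if (v$disease == disease && v$state == state) return(v)
  stop("no view for ", disease, ",", state)
}

# a view over the raw (unsimplified) graph, for oracle comparisons
raw_view <- function(kb, disease, state, ev) {
  if (!inherits(ev, "ducg_evidence")) ev <- ducg_evidence(ev)
  structure(list(kb = kb, disease = disease, state = state,
                 root = if (!is.null(kb$sa[[disease]])) kb$sa[[disease]]$bx
                        else disease,
                 evidence = ev),
            class = "ducg_view")
}

zetas_named <- function(views, ev, leak = 0.01) {
  z <- vapply(views, evaluate, numeric(1), ev = ev, leak = leak)
  names(z) <- vapply(views, function(v) paste0(v$disease, ",", v$state),
                     character(1))
  z
}
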