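# Packaged knowledge bases and seeded generators.
#
# The laryngopharyngeal-reflux module carries the published prior
# (Pr abnormal = 0.03), risk-factor gate and 10x multiplier; its causal
# strengths, and everything in the other fixtures beyond the published
# disease priors and identifiers, are synthetic values fixed here once so
# golden tests stay stable.

b2 <- function(p) c(1 - p, p)  # binary prior, normal state first
row1 <- function(...) matrix(c(...), nrow = 1)  # single-abnormal-state strength

#' The laryngopharyngeal reflux sub-DUCG
#'
#' One-disease module for laryngopharyngeal reflux (LPR): disease root
#' `B23` with abnormal prior 0.03, risk factor `X74` (history of reflux
#' esophagitis) wired through gate `SG23` whose triggered state multiplies
#' the prior by 10 (so the conditional root `BX23` has abnormal mass 0.3
#' when `X74 = 1`), gold-standard manifestation `SX160` (response to
#' proton pump inhibitors), and nonspecific manifestations with synthetic
#' strengths.
#'
#' @return A `ducg_sub`.
#' @examples
#' compute_bx_prior(lpr_subducg(), "B23", c(X74 = 1))
#' @export
lpr_subducg <- function() {
  ducg_kb(
    variables = list(
      ducg_variable("B23", "B", prior = b2(0.03),
                    label = "Laryngopharyngeal reflux"),
      ducg_variable("BX23", "BX", label = "LPR incidence given risk factors"),
      ducg_variable("SG23", "SG", label = "LPR risk-factor gate"),
      ducg_variable("X74", "X", label = "History of reflux esophagitis"),
      ducg_variable("X85", "X", label = "Sore throat"),
      ducg_variable("X21", "X", label = "Hoarseness"),
      ducg_variable("X45", "X", label = "Foreign body sensation in throat"),
      ducg_variable("X150", "X", label = "Throat clearing"),
      ducg_variable("X153", "X", label = "Vocal cord edema"),
      ducg_variable("X158", "X", label = "Pharyngeal pH monitoring positive"),
      ducg_variable("SX160", "SX",
                    label = "Proton pump inhibitors are effective"),
      ducg_variable("C23", "C", label = "LPR manifestation group")),
    links = list(
      ducg_link("X85", "BX23", strength = row1(0, 0.40)),
      ducg_link("X21", "BX23", strength = row1(0, 0.50)),
      ducg_link("X45", "BX23", strength = row1(0, 0.40)),
      ducg_link("X150", "BX23", strength = row1(0, 0.55)),
      ducg_link("X153", "BX23", strength = row1(0, 0.45)),
      ducg_link("X158", "BX23", strength = row1(0, 0.70)),
      ducg_link("SX160", "BX23", strength = row1(0, 0.90))),
    gates = list(
      ducg_gate("SG23", rows = list(list(state = 1L, expr = "X74=1")))),
    sa = list(ducg_sa("B23", "BX23", "SG23", factors = c(1, 10))),
    name = "lpr", sub = TRUE)
}

chronic_laryngitis_subducg <- function() {
  ducg_kb(
    variables = list(
      ducg_variable("B11", "B", prior = b2(0.04),
                    label = "Chronic laryngitis"),
      ducg_variable("BX11", "BX",
                    label = "Chronic laryngitis incidence given risk factors"),
      ducg_variable("SG11", "SG", label = "Chronic laryngitis risk gate"),
      ducg_variable("X5", "X", label = "Subacute stage"),
      ducg_variable("X52", "X", label = "Male sex"),
      ducg_variable("X7", "X", n_states = 5L, label = "Age group"),
      ducg_variable("X85", "X", label = "Sore throat"),
      ducg_variable("X21", "X", label = "Hoarseness"),
      ducg_variable("X45", "X", label = "Foreign body sensation in throat"),
      ducg_variable("X44", "X", label = "Throat itching"),
      ducg_variable("X51", "X", label = "Dry throat"),
      ducg_variable("X22", "X", label = "Cough"),
      ducg_variable("X153", "X", label = "Vocal cord edema")),
    links = list(
      ducg_link("X85", "BX11", strength = row1(0, 0.50)),
      ducg_link("X21", "BX11", strength = row1(0, 0.70)),
      ducg_link("X45", "BX11", strength = row1(0, 0.30)),
      ducg_link("X44", "BX11", strength = row1(0, 0.30)),
      ducg_link("X51", "BX11", strength = row1(0, 0.40)),
      ducg_link("X22", "BX11", strength = row1(0, 0.35)),
      ducg_link("X153", "BX11", strength = row1(0, 0.30))),
    gates = list(
      ducg_gate("SG11", rows = list(
        list(state = 2L, expr = "X5=1 & X52=1"),
        list(state = 1L, expr = "X5=1 | X52=1 | X7=4")))),
    sa = list(ducg_sa("B11", "BX11", "SG11", factors = c(1, 3, 5))),
    name = "chronic_laryngitis", sub = TRUE)
}

chronic_pharyngitis_subducg <- function() {
  ducg_kb(
    variables = list(
      ducg_variable("B12", "B", prior = b2(0.09),
                    label = "Chronic pharyngitis"),
      ducg_variable("X85", "X", label = "Sore throat"),
      ducg_variable("X21", "X", label = "Hoarseness"),
      ducg_variable("X45", "X", label = "Foreign body sensation in throat"),
      ducg_variable("X44", "X", label = "Throat itching"),
      ducg_variable("X51", "X", label = "Dry throat"),
      ducg_variable("X23", "X", label = "Expectoration"),
      ducg_variable("X150", "X", label = "Throat clearing")),
    links = list(
      ducg_link("X85", "B12", strength = row1(0, 0.45)),
      ducg_link("X21", "B12", strength = row1(0, 0.15)),
      ducg_link("X45", "B12", strength = row1(0, 0.60)),
      ducg_link("X44", "B12", strength = row1(0, 0.50)),
      ducg_link("X51", "B12", strength = row1(0, 0.50)),
      ducg_link("X23", "B12", strength = row1(0, 0.30)),
      ducg_link("X150", "B12", strength = row1(0, 0.40))),
    name = "chronic_pharyngitis", sub = TRUE)
}

#' A three-disease differential-diagnosis knowledge base
#'
#' Merge of three single-disease modules — chronic laryngitis (prior
#' 0.04), chronic pharyngitis (prior 0.09) and laryngopharyngeal reflux
#' (prior 0.03) — sharing the overlapping throat manifestations, so the
#' same symptom (e.g. hoarseness `X21`) is evidence for several diseases
#' at once. Chronic laryngitis and LPR carry risk-factor gates; chronic
#' pharyngitis has none and exercises the raw-prior pass-through.
#'
#' @return A complete `ducg`.
#' @examples
#' diagnose(three_disease_kb(), c(X21 = 1, X45 = 1, X150 = 1))
#' @export
three_disease_kb <- function() {
  merge_subgraphs(list(chronic_laryngitis_subducg(),
                       chronic_pharyngitis_subducg(),
                       lpr_subducg()),
                  name = "three_disease")
}

# disease roster of the complete sore-throat graph (indices have a gap:
# there is no B21)
SORE_THROAT_DISEASES <- data.frame(
  id = c("B1", "B2", "B3", "B4", "B11", "B12", "B9", "B19", "B7",
         "B5", "B17", "B8", "B10", "B13", "B18", "B22", "B20", "B26",
         "B24", "B25", "B6", "B14", "B15", "B28", "B23", "B27", "B16"),
  label = c("Acute tonsillitis", "Acute pharyngitis", "Acute epiglottitis",
            "Acute laryngitis", "Chronic laryngitis", "Chronic pharyngitis",
            "Chronic tonsillitis", "Peritonsillitis", "Peritonsillar abscess",
            "Pharyngeal burn", "Closed laryngeal trauma",
            "Pharyngeal foreign body", "Cancer of the larynx",
            "Tonsil carcinoma", "Carcinoma of hypopharynx", "Tonsil lymphoma",
            "Laryngeal tuberculosis", "Pharyngeal tuberculosis",
            "Laryngeal syphilis", "Pharyngeal syphilis",
            "Glossopharyngeal neuralgia", "Styloid process syndrome",
            "Infectious mononucleosis", "Coronary heart disease",
            "Laryngopharyngeal reflux", "Upper respiratory tract infection",
            "Throat ulcers"),
  stringsAsFactors = FALSE)

#' Skeleton of the complete sore-throat knowledge base
#'
#' Structure-only placeholder with the full roster of 27 sore-throat
#' related diseases under their published identifiers (note the index gap:
#' no B21), each linked to the shared chief-complaint manifestation `X85`.
#' Published priors are used where available (B11, B12, B23); all other
#' priors and all strengths are synthetic placeholders.
#'
#' @return A complete `ducg` with exactly 27 disease roots.
#' @export
sore_throat_skeleton <- function() {
  known_priors <- c(B11 = 0.04, B12 = 0.09, B23 = 0.03)
  variables <- c(
    lapply(seq_len(nrow(SORE_THROAT_DISEASES)), function(i) {
      id <- SORE_THROAT_DISEASES$id[i]
      p <- if (id %in% names(known_priors)) known_priors[[id]] else 0.01
      ducg_variable(id, "B", prior = b2(p),
                    label = SORE_THROAT_DISEASES$label[i])
    }),
    list(ducg_variable("X85", "X", label = "Sore throat")))
  links <- lapply(SORE_THROAT_DISEASES$id, function(id)
    ducg_link("X85", id, strength = row1(0, 0.5)))
  ducg_kb(variables, links, name = "sore_throat_skeleton")
}

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Parameters for a seeded random knowledge base
#'
#' @param seed Integer seed; identical seed and parameters yield an
#'   identical knowledge base.
#' @param n_diseases,n_manifestations Graph size.
#' @param unique_per_disease Distinguishing manifestations exclusive to
#'   each disease.
#' @param shared_links Additional links per disease into the shared
#'   manifestation pool.
#' @param unique_strength,shared_strength Ranges the corresponding
#'   strengths are drawn from.
#' @param prior_range Range of disease abnormal prior mass.
#' @param max_states Maximum state count; disease and manifestation state
#'   counts are drawn in `2:max_states`.
#' @param name Knowledge-base name.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed, n_diseases = 3L, n_manifestations = 9L,
                         unique_per_disease = 1L, shared_links = 2L,
                         unique_strength = c(0.8, 0.95),
                         shared_strength = c(0.2, 0.6),
                         prior_range = c(0.01, 0.1),
                         max_states = 2L, name = NULL) {
  spec <- list(seed = as.integer(seed), n_diseases = as.integer(n_diseases),
               n_manifestations = as.integer(n_manifestations),
               unique_per_disease = as.integer(unique_per_disease),
               shared_links = as.integer(shared_links),
               unique_strength = unique_strength,
               shared_strength = shared_strength,
               prior_range = prior_range, max_states = as.integer(max_states),
               name = name %||% paste0("random_kb_seed", seed))
  if (spec$unique_per_disease * spec$n_diseases > spec$n_manifestations)
    stop("infeasible density: ", spec$n_diseases, " diseases x ",
         spec$unique_per_disease, " unique manifestations exceed the pool of ",
         spec$n_manifestations, call. = FALSE)
  structure(spec, class = "fixture_spec")
}

#' Generate a seeded random knowledge base
#'
#' Builds a two-layer disease/manifestation graph from a [fixture_spec()]:
#' every disease gets a block of exclusive (distinguishing) manifestations
#' with strengths from `unique_strength` plus links into the shared pool
#' with strengths from `shared_strength`. Generation is reproducible and
#' leaves the caller's RNG state untouched.
#'
#' @param spec A [fixture_spec()].
#' @return A complete `ducg`.
#' @examples
#' kb <- random_kb(fixture_spec(1))
#' @export
random_kb <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    state_opts <- seq.int(2L, spec$max_states)
    pick_states <- function(n) {
      if (length(state_opts) == 1L) rep(state_opts, n)
      else sample(state_opts, n, replace = TRUE)
    }
    d_states <- pick_states(spec$n_diseases)
    m_states <- pick_states(spec$n_manifestations)
    d_ids <- paste0("B", seq_len(spec$n_diseases))
    m_ids <- paste0("X", 100L + seq_len(spec$n_manifestations))
    variables <- c(
      lapply(seq_len(spec$n_diseases), function(i) {
        total <- stats::runif(1, spec$prior_range[1], spec$prior_range[2])
        mass <- stats::runif(d_states[i] - 1L)
        mass <- total * mass / sum(mass)
        ducg_variable(d_ids[i], "B", n_states = d_states[i],
                      prior = c(1 - total, mass),
                      label = paste("Disease", i))
      }),
      lapply(seq_len(spec$n_manifestations), function(j)
        ducg_variable(m_ids[j], "X", n_states = m_states[j],
                      label = paste("Manifestation", j))))
    n_unique <- spec$unique_per_disease * spec$n_diseases
    shared_pool <- m_ids[setdiff(seq_len(spec$n_manifestations),
                                 seq_len(n_unique))]
    rand_strength <- function(child_i, parent_i, range) {
      m <- matrix(0, nrow = m_states[child_i] - 1L, ncol = d_states[parent_i])
      for (j in seq_len(d_states[parent_i] - 1L)) {
        col <- stats::runif(nrow(m), range[1], range[2])
        m[, j + 1L] <- if (sum(col) > 1) col / (sum(col) + 0.05) else col
      }
      m
    }
    links <- list()
    for (i in seq_len(spec$n_diseases)) {
      mine <- (i - 1L) * spec$unique_per_disease + seq_len(spec$unique_per_disease)
      for (j in mine)
        links[[length(links) + 1L]] <-
          ducg_link(m_ids[j], d_ids[i],
                    strength = rand_strength(j, i, spec$unique_strength))
      if (spec$shared_links > 0L && length(shared_pool) > 0L) {
        take <- sample(shared_pool, min(spec$shared_links, length(shared_pool)))
        for (id in take) {
          j <- match(id, m_ids)
          links[[length(links) + 1L]] <-
            ducg_link(id, d_ids[i],
                      strength = rand_strength(j, i, spec$shared_strength))
        }
      }
    }
    ducg_kb(variables, links, name = spec$name)
  })
}

#' Sample labelled cases from a knowledge base
#'
#' Draws cases from the generative semantics under the single-fault
#' premise: one disease is drawn with probability proportional to its
#' abnormal prior mass (all others held normal), an abnormal state of that
#' disease is drawn from its prior, and every consequence variable is
#' forward-sampled from its r-weighted mixture distribution. All non-risk
#' consequence variables are reported as observed evidence, and each case
#' carries its generating disease as the gold label.
#'
#' @param kb A `ducg`.
#' @param n Number of cases.
#' @param seed Integer seed.
#' @return List of `list(truth, state, evidence)` entries.
#' @export
sample_cases <- function(kb, n, seed = 1L) {
  diseases <- disease_ids(kb)
  mass <- vapply(diseases, function(d) 1 - kb$variables[[d]]$prior[1],
                 numeric(1))
  graph <- links_graph(kb)
  topo <- names(igraph::topo_sort(graph, mode = "out"))
  rf <- risk_factor_ids(kb)
  kinds <- vapply(kb$variables, function(v) v$kind, character(1))
  observe <- setdiff(names(kb$variables)[kinds %in% c("X", "SX")], rf)
  with_seed(seed, lapply(seq_len(n), function(i) {
    d <- sample(diseases, 1, prob = mass)
    pr <- kb$variables[[d]]$prior
    s <- sample(seq_along(pr) - 1L, 1, prob = c(0, pr[-1]))
    states <- setNames(integer(0), character(0))
    for (dd in diseases) {
      states[dd] <- if (dd == d) s else 0L
      states[disease_root_var(kb, dd)] <- states[dd]
    }
    states[rf] <- 0L
    for (v in topo) {
      if (v %in% names(states)) next
      if (kinds[[v]] == "D") {
        states[v] <- sample(seq_len(kb$variables[[v]]$n_states) - 1L, 1,
                            prob = kb$variables[[v]]$prior)
        next
      }
      dist <- child_dist(kb, v, as.list(states[parent_ids(kb, v)]))
      states[v] <- sample(seq_along(dist) - 1L, 1, prob = dist)
    }
    list(truth = d, state = s,
         evidence = ducg_evidence(states[observe], kb = kb))
  }))
}
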