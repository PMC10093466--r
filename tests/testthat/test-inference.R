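test_that("simplification drops diseases that cannot reach abnormal evidence", {
  kb <- two_disease_kb()
  ev <- ducg_evidence(c(X10 = 1), kb = kb)  # only B1's manifestation
  s <- simplify(kb, ev)
  expect_setequal(disease_ids(s), "B1")
  expect_false("X11" %in% names(s$variables))  # barren leaf of dropped B2
})

test_that("with no evidence only barren removal applies", {
  kb <- two_disease_kb()
  s <- simplify(kb, ducg_evidence(c()))
  expect_true(attr(s, "no_abnormal"))
  expect_setequal(disease_ids(s), c("B1", "B2"))
  expect_length(Filter(function(v) v$kind %in% c("X", "SX"), s$variables), 0L)
})

test_that("all three diseases survive the shared-symptom presentation", {
  kb <- three_disease_kb()
  ev <- ducg_evidence(c(X85 = 1, X21 = 1, X45 = 1), kb = kb)
  s <- simplify(kb, ev)
  expect_setequal(disease_ids(s), c("B11", "B12", "B23"))
  # observed variables are all retained
  expect_true(all(names(ev$observations) %in% names(s$variables)))
})

test_that("evidence naming unknown variables is rejected", {
  expect_error(simplify(two_disease_kb(), c(X999 = 1)), "X999")
  expect_error(ducg_evidence(c(B1 = 1), kb = two_disease_kb()),
               "not directly observable")
})

test_that("deterministic contradictions eliminate hypothesis states", {
  # B1's only manifestation is certain (a = 1) but observed normal
  kb <- ducg_kb(list(ducg_variable("B1", "B", prior = c(0.9, 0.1)),
                     ducg_variable("B2", "B", prior = c(0.9, 0.1)),
                     ducg_variable("X10", "X"),
                     ducg_variable("X11", "X")),
                list(ducg_link("X10", "B1", strength = row1(0, 1)),
                     ducg_link("X11", "B2", strength = row1(0, 0.5)),
                     ducg_link("X11", "B1", strength = row1(0, 0.2))),
                name = "contradiction")
  ev <- ducg_evidence(c(X10 = 0, X11 = 1), kb = kb)
  views <- decompose(simplify(kb, ev), ev)
  expect_setequal(vapply(views, function(v) v$disease, character(1)), "B2")
})

test_that("decomposition yields one view per abnormal state per root", {
  kb3 <- three_disease_kb()
  ev <- ducg_evidence(c(X85 = 1, X21 = 1, X45 = 1), kb = kb3)
  views <- decompose(simplify(kb3, ev), ev)
  expect_length(views, 3L)
  expect_identical(vapply(views, function(v) v$disease, character(1)),
                   c("B11", "B12", "B23"))  # ascending index order
  # a three-state disease contributes two hypotheses
  kb <- ducg_kb(list(ducg_variable("B1", "B", n_states = 3L,
                                   prior = c(0.9, 0.06, 0.04)),
                     ducg_variable("X2", "X")),
                list(ducg_link("X2", "B1",
                               strength = matrix(c(0, 0.5, 0.9), 1))),
                name = "multistate")
  ev2 <- ducg_evidence(c(X2 = 1), kb = kb)
  views2 <- decompose(simplify(kb, ev2), ev2)
  expect_length(views2, 2L)
  expect_identical(vapply(views2, function(v) v$state, integer(1)), 1:2)
})

test_that("single-link joint probabilities match hand arithmetic", {
  kb <- one_link_kb(p = 0.1, a = 0.8)
  v_ab <- view_for(kb, c(X2 = 1), "B1")
  expect_equal(evaluate(v_ab), 0.1 * 0.8)
  v_no <- raw_view(kb, "B1", 1L, ducg_evidence(c(X2 = 0)))
  expect_equal(evaluate(v_no), 0.1 * 0.2)
})

test_that("unobserved intermediate variables are marginalized exactly", {
  kb <- chain_kb(p = 0.1, a12 = 0.8, a23 = 0.5)
  v <- view_for(kb, c(X3 = 1), "B1")
  expect_equal(evaluate(v), 0.1 * 0.8 * 0.5)
  # observing the intermediate normal blocks the chain
  v2 <- raw_view(kb, "B1", 1L, ducg_evidence(c(X2 = 0, X3 = 1)))
  expect_equal(evaluate(v2), 0)
  # X3 normal: marginalize X2 over both states
  v3 <- raw_view(kb, "B1", 1L, ducg_evidence(c(X3 = 0)))
  expect_equal(evaluate(v3), 0.1 * (0.8 * 0.5 + 0.2))
})

test_that("posteriors normalize and rank deterministically", {
  res <- posterior(c("B2,1" = 0.03, "B1,1" = 0.01))
  expect_equal(res$posterior, c(0.75, 0.25))
  expect_identical(res$disease, c("B2", "B1"))
  single <- posterior(c("B1,1" = 0.4))
  expect_equal(single$posterior, 1)
  # exact ties break by ascending variable index
  tied <- posterior(c("B7,1" = 0.2, "B2,1" = 0.2))
  expect_identical(tied$disease, c("B2", "B7"))
  zero <- posterior(c("B1,1" = 0, "B2,1" = 0))
  expect_identical(nrow(zero), 0L)
  expect_true(attr(zero, "no_explanation"))
  expect_error(posterior(c("B1,1" = -0.1)), "negative")
})

test_that("diagnose with empty evidence ranks by adjusted priors", {
  kb <- three_disease_kb()
  res <- diagnose(kb, c())
  expect_identical(res$disease, c("B12", "B11", "B23"))  # 0.09 > 0.04 > 0.03
  expect_equal(res$posterior, c(0.09, 0.04, 0.03) / 0.16)
  expect_equal(sum(res$posterior), 1)
})

test_that("risk factors rescale the prior mass before any evidence", {
  kb <- three_disease_kb()
  z1 <- diagnose(kb, c(X74 = 1))
  z0 <- diagnose(kb, c(X74 = 0))
  r1 <- z1$zeta[z1$disease == "B23"]
  r0 <- z0$zeta[z0$disease == "B23"]
  expect_equal(r1 / r0, 10)
  # other diseases untouched
  expect_equal(z1$zeta[z1$disease == "B12"], z0$zeta[z0$disease == "B12"])
})

test_that("normal evidence on a linked manifestation never raises zeta", {
  kb <- three_disease_kb()
  base <- diagnose(kb, c(X21 = 1, X45 = 1))
  more <- diagnose(kb, c(X21 = 1, X45 = 1, X22 = 0, X51 = 0))
  for (d in base$disease) {
    expect_lte(more$zeta[more$disease == d],
               base$zeta[base$disease == d] + 1e-15)
  }
})

test_that("isolated abnormal evidence costs exactly one leak factor", {
  kb <- two_disease_kb()
  leak <- 0.01
  base <- diagnose(kb, c(X10 = 1), leak = leak)
  # X11 is only reachable from B2: for B1 it is isolated
  more <- diagnose(kb, c(X10 = 1, X11 = 1), leak = leak)
  z_b1_base <- base$zeta[base$disease == "B1"]
  z_b1_more <- more$zeta[more$disease == "B1"]
  expect_equal(z_b1_more, z_b1_base * leak)
  # and the interpretation classifies it as isolated
  interp <- attr(more, "interpretations")[[
    which(vapply(attr(more, "views"), function(v) v$disease, character(1)) == "B1")]]
  expect_identical(interp$isolated, "X11")
})

test_that("posteriors sum to one whenever evidence is explainable", {
  kb <- three_disease_kb()
  for (ev in list(c(X21 = 1), c(X85 = 1, X44 = 1, X22 = 0),
                  c(X150 = 1, X153 = 1, X74 = 1))) {
    res <- diagnose(kb, ev)
    expect_equal(sum(res$posterior), 1, tolerance = 1e-9)
  }
})

test_that("an observed gold-standard manifestation flags the disease", {
  kb <- three_disease_kb()
  res <- diagnose(kb, c(X21 = 1, SX160 = 1))
  expect_true(res$gold_standard[res$disease == "B23"])
  expect_false(any(res$gold_standard[res$disease != "B23"]))
})

test_that("discriminating manifestations outrank shared ones", {
  # X10/X11 each separate one disease (0.9 vs absent); X12 is shared
  # equally and carries no discriminating value
  kb <- two_disease_kb(a_unique = 0.9, a_shared = 0.5)
  sug <- suggest_next(kb, c(), top_m = 3L)
  expect_identical(sug$variable[1], "X10")  # tie with X11, index order
  expect_identical(sug$variable[3], "X12")
  expect_gt(sug$gain[1], sug$gain[3])
})

test_that("suggestions are empty when everything is observed or confirmed", {
  kb <- two_disease_kb()
  all_obs <- c(X10 = 1, X11 = 0, X12 = 1)
  expect_identical(nrow(suggest_next(kb, all_obs)), 0L)
  # confirmation threshold reached -> nothing to ask
  sug <- suggest_next(kb, c(X12 = 1), confirm = 0)
  expect_identical(nrow(sug), 0L)
})

test_that("symmetric candidates tie and order by variable index", {
  kb <- ducg_kb(list(ducg_variable("B1", "B", prior = c(0.95, 0.05)),
                     ducg_variable("B2", "B", prior = c(0.95, 0.05)),
                     ducg_variable("X20", "X"),
                     ducg_variable("X21", "X"),
                     ducg_variable("X22", "X")),
                list(ducg_link("X20", "B1", strength = row1(0, 0.6)),
                     ducg_link("X20", "B2", strength = row1(0, 0.6)),
                     ducg_link("X21", "B1", strength = row1(0, 0.6)),
                     ducg_link("X21", "B2", strength = row1(0, 0.6)),
                     ducg_link("X22", "B1", strength = row1(0, 0.6)),
                     ducg_link("X22", "B2", strength = row1(0, 0.6))),
                name = "symmetric")
  sug <- suggest_next(kb, c(X20 = 1))
  expect_identical(sug$variable, c("X21", "X22"))
  expect_equal(sug$gain[1], sug$gain[2], tolerance = 1e-12)
})
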