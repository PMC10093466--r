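test_that("risk-factor gate rescales the disease prior", {
  kb <- lpr_subducg()
  expect_equal(unname(compute_bx_prior(kb, "B23", c(X74 = 1))["1"]), 0.3)
  expect_equal(unname(compute_bx_prior(kb, "B23", c(X74 = 0))["1"]), 0.03)
  # unobserved risk factors default to absent
  expect_equal(unname(compute_bx_prior(kb, "B23", NULL)["1"]), 0.03)
  # the returned vector is a distribution
  expect_equal(sum(compute_bx_prior(kb, "B23", c(X74 = 1))), 1)
})

test_that("scaled abnormal mass is clipped at 1", {
  kb <- ducg_kb(list(ducg_variable("B1", "B", prior = c(0.97, 0.03)),
                     ducg_variable("BX1", "BX"),
                     ducg_variable("SG1", "SG"),
                     ducg_variable("X9", "X"),
                     ducg_variable("X8", "X")),
                list(ducg_link("X8", "BX1", strength = row1(0, 0.5))),
                list(ducg_gate("SG1", rows = list(list(state = 1, expr = "X9=1")))),
                list(ducg_sa("B1", "BX1", "SG1", factors = c(1, 50))),
                name = "clip")
  pr <- compute_bx_prior(kb, "B1", c(X9 = 1))
  expect_equal(unname(pr["1"]), 1)   # 50 x 0.03 clipped
  expect_equal(unname(pr["0"]), 0)
})

test_that("gates evaluate first-match-wins with a remnant default", {
  gate <- ducg_gate("SG1", rows = list(
    list(state = 2L, expr = "X5=1 & X52=1"),
    list(state = 1L, expr = "X5=1 | X52=1 | X7=4")),
    remnant = 0L)
  expect_identical(evaluate_gate(gate, c(X5 = 1, X52 = 1)), 2L)
  expect_identical(evaluate_gate(gate, c(X5 = 1)), 1L)
  expect_identical(evaluate_gate(gate, c(X7 = 4)), 1L)
  expect_identical(evaluate_gate(gate, c(X7 = 2)), 0L)
  expect_identical(evaluate_gate(gate, c()), 0L)
  # negation and parentheses
  gate2 <- ducg_gate("SG2", rows = list(
    list(state = 1L, expr = "!(X1=1) & X2=1")))
  expect_identical(evaluate_gate(gate2, c(X2 = 1)), 1L)
  expect_identical(evaluate_gate(gate2, c(X1 = 1, X2 = 1)), 0L)
})

test_that("malformed gate expressions are rejected at declaration", {
  expect_error(ducg_gate("SG1", rows = list(list(state = 1, expr = "X1=1; rm()"))),
               "unsupported tokens")
  expect_error(ducg_gate("SG1", rows = list(list(state = 1, expr = "system('x')"))),
               "unsupported tokens")
})

test_that("a multiplier of 1 on every gate state reproduces the raw prior", {
  kb <- ducg_kb(list(ducg_variable("B1", "B", n_states = 3L,
                                   prior = c(0.92, 0.05, 0.03)),
                     ducg_variable("BX1", "BX", n_states = 3L),
                     ducg_variable("SG1", "SG"),
                     ducg_variable("X9", "X"),
                     ducg_variable("X8", "X")),
                list(ducg_link("X8", "BX1",
                               strength = matrix(c(0, 0.4, 0.2), 1))),
                list(ducg_gate("SG1", rows = list(list(state = 1, expr = "X9=1")))),
                list(ducg_sa("B1", "BX1", "SG1", factors = c(1, 1))),
                name = "unit_factor")
  for (risk in list(c(X9 = 0), c(X9 = 1)))
    expect_equal(unname(compute_bx_prior(kb, "B1", risk)),
                 c(0.92, 0.05, 0.03))
})

test_that("diseases without a gate pass their prior through", {
  kb <- two_disease_kb()
  expect_equal(unname(compute_bx_prior(kb, "B1", c())), c(0.95, 0.05))
})

test_that("sa records must keep the remnant factor at 1", {
  expect_error(
    ducg_kb(list(ducg_variable("B1", "B", prior = c(0.97, 0.03)),
                 ducg_variable("BX1", "BX"),
                 ducg_variable("SG1", "SG"),
                 ducg_variable("X9", "X"),
                 ducg_variable("X8", "X")),
            list(ducg_link("X8", "BX1", strength = row1(0, 0.5))),
            list(ducg_gate("SG1", rows = list(list(state = 1, expr = "X9=1")))),
            list(ducg_sa("B1", "BX1", "SG1", factors = c(2, 10)))),
    "remnant")
})
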