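test_that("variable constructor enforces prior and kind rules", {
  expect_error(ducg_variable("B1", "B"), "requires a prior")
  expect_error(ducg_variable("B1", "B", prior = c(0.5, 0.4)), "sum to 1")
  expect_error(ducg_variable("X1", "X", prior = c(0.5, 0.5)),
               "must not carry a prior")
  expect_error(ducg_variable("BX1", "BX", prior = c(0.7, 0.3)),
               "must not carry a prior")
  v <- ducg_variable("B23", "B", prior = c(0.97, 0.03))
  expect_identical(v$n_states, 2L)
})

test_that("link strengths outside [0, 1] are rejected", {
  expect_error(ducg_link("X2", "B1", strength = row1(0, 1.2)), "\\[0, 1\\]")
  expect_error(ducg_link("X2", "B1", r = -1, strength = row1(0, 0.5)),
               "positive")
})

test_that("a knowledge base must declare variables with unique ids", {
  expect_error(ducg_kb(list()), "at least one variable")
  expect_error(
    ducg_kb(list(ducg_variable("B1", "B", prior = c(0.9, 0.1)),
                 ducg_variable("B1", "B", prior = c(0.9, 0.1)))),
    "duplicate")
})

test_that("packaged LPR module loads with the published prior", {
  path <- system.file("extdata", "kb", "lpr.yaml", package = "ducgdx")
  kb <- load_kb(path)
  expect_s3_class(kb, "ducg_sub")
  expect_equal(kb$variables[["B23"]]$prior, c(0.97, 0.03))
  expect_length(validate_kb(kb), 0L)
})

test_that("loading rejects dangling references and empty KBs", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    name = "broken",
    variables = list(list(id = "B1", kind = "B", states = 2,
                          prior = c(0.9, 0.1))),
    links = list(list(child = "X999", parent = "B1",
                      strength = list(c(0, 0.5))))), tmp)
  expect_error(load_kb(tmp), "X999")

  tmp2 <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(name = "empty", variables = list()), tmp2)
  expect_error(load_kb(tmp2), "at least one disease root|no variables")
})

test_that("validator flags conditional-probability overflow exactly", {
  # three-state child: one parent state drives total abnormal mass to 1.3
  kb <- ducg_kb(list(ducg_variable("B1", "B", prior = c(0.9, 0.1)),
                     ducg_variable("X2", "X", n_states = 3L)),
                list(ducg_link("X2", "B1",
                               strength = matrix(c(0, 0, 0.7, 0.6), 2))),
                check = FALSE)
  codes <- vapply(validate_kb(kb), function(f) f$code, character(1))
  expect_true("cpt_overflow" %in% codes)

  # two parents at 0.8 each: the r-weighted mixture stays at 0.8 <= 1
  kb2 <- ducg_kb(list(ducg_variable("B1", "B", prior = c(0.9, 0.1)),
                      ducg_variable("B2", "B", prior = c(0.9, 0.1)),
                      ducg_variable("X3", "X")),
                 list(ducg_link("X3", "B1", r = 1, strength = row1(0, 0.8)),
                      ducg_link("X3", "B2", r = 1, strength = row1(0, 0.8))))
  expect_length(validation_errors <- Filter(function(f) f$level == "error",
                                            validate_kb(kb2)), 0L)
})

test_that("validator detects cycles", {
  kb <- ducg_kb(list(ducg_variable("B1", "B", prior = c(0.9, 0.1)),
                     ducg_variable("X2", "X"),
                     ducg_variable("X3", "X")),
                list(ducg_link("X2", "B1", strength = row1(0, 0.5)),
                     ducg_link("X3", "X2", strength = row1(0, 0.5)),
                     ducg_link("X2", "X3", strength = row1(0, 0.5))),
                check = FALSE)
  codes <- vapply(validate_kb(kb), function(f) f$code, character(1))
  expect_true("cycle" %in% codes)
})

test_that("merging unifies shared manifestations with the union of links", {
  kb <- three_disease_kb()
  hoarseness_parents <- vapply(
    Filter(function(l) l$child == "X21", kb$links),
    function(l) l$parent, character(1))
  expect_setequal(hoarseness_parents, c("BX11", "B12", "BX23"))
  # provenance remembers the contributing module
  expect_identical(unname(kb$provenance[["B12"]]), "chronic_pharyngitis")
})

test_that("merge is an identity on a single module and order-independent", {
  lpr <- lpr_subducg()
  expect_true(kb_identical(merge_subgraphs(list(lpr)), lpr))
  parts <- list(chronic_laryngitis_subducg(), chronic_pharyngitis_subducg(),
                lpr_subducg())
  ab <- merge_subgraphs(parts)
  ba <- merge_subgraphs(rev(parts))
  expect_true(kb_identical(ab, ba))
  # associativity: merge(merge(a, b), c) == merge(a, merge(b, c))
  left <- merge_subgraphs(list(merge_subgraphs(parts[1:2]), parts[[3]]))
  right <- merge_subgraphs(list(parts[[1]], merge_subgraphs(parts[2:3])))
  expect_true(kb_identical(left, right))
})

test_that("merge conflicts name the offending variable", {
  a <- ducg_kb(list(ducg_variable("B1", "B", prior = c(0.9, 0.1)),
                    ducg_variable("X5", "X")),
               list(ducg_link("X5", "B1", strength = row1(0, 0.5))),
               name = "a", sub = TRUE)
  b <- ducg_kb(list(ducg_variable("B2", "B", prior = c(0.9, 0.1)),
                    ducg_variable("X5", "X", n_states = 3L)),
               list(ducg_link("X5", "B2",
                              strength = matrix(c(0, 0.2, 0, 0.2), 2))),
               name = "b", sub = TRUE)
  expect_error(merge_subgraphs(list(a, b)), "X5")
})

test_that("knowledge bases round-trip through YAML and JSON", {
  for (kb in list(lpr_subducg(), three_disease_kb(), sore_throat_skeleton())) {
    for (ext in c(".yaml", ".json")) {
      tmp <- withr::local_tempfile(fileext = ext)
      write_kb(kb, tmp)
      expect_true(kb_identical(load_kb(tmp), kb))
    }
  }
  # packaged directory-of-subgraphs form merges to the in-code fixture
  dir <- system.file("extdata", "kb", "three_disease", package = "ducgdx")
  expect_true(kb_identical(load_kb(dir), three_disease_kb()))
  parts <- load_kb(dir, merge = FALSE)
  expect_length(parts, 3L)
})
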