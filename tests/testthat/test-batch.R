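test_that("accuracy arithmetic handles the printed edge cases", {
  expect_equal(accuracy(9, 10), 90)
  expect_equal(accuracy(10, 10), 100)
  expect_warning(zero <- accuracy(0, 0), "no test cases")
  expect_equal(zero, 0)
  expect_error(accuracy(11, 10), "exceeds")
})

test_that("report rows, totals and JSON agree", {
  kb <- random_kb(fixture_spec(31, n_diseases = 3, n_manifestations = 9,
                               unique_per_disease = 2))
  cases <- sample_cases(kb, 40, seed = 32)
  report <- evaluate_batch(kb, cases)
  expect_equal(report$totals$test_cases, sum(report$per_disease$test_cases))
  expect_equal(report$totals$true_cases, sum(report$per_disease$true_cases))
  expect_equal(report$totals$accuracy,
               100 * report$totals$true_cases / report$totals$test_cases)
  per_row <- with(report$per_disease,
                  ifelse(test_cases == 0, 0, 100 * true_cases / test_cases))
  expect_equal(report$per_disease$accuracy, per_row)
  expect_equal(nrow(report$misdiagnoses),
               report$totals$test_cases - report$totals$true_cases)
  parsed <- jsonlite::fromJSON(eval_report_json(report))
  expect_equal(parsed$totals$accuracy, report$totals$accuracy)
  expect_equal(parsed$per_disease$true_cases, report$per_disease$true_cases)
})

test_that("fully deterministic evidence is always recovered", {
  kb <- ducg_kb(list(ducg_variable("B1", "B", prior = c(0.9, 0.1)),
                     ducg_variable("B2", "B", prior = c(0.9, 0.1)),
                     ducg_variable("X10", "X"),
                     ducg_variable("X11", "X")),
                list(ducg_link("X10", "B1", strength = row1(0, 1)),
                     ducg_link("X11", "B2", strength = row1(0, 1))),
                name = "det2")
  cases <- sample_cases(kb, 20, seed = 2)
  report <- evaluate_batch(kb, cases)
  expect_equal(report$totals$accuracy, 100)
})

test_that("unlabelled cases are skipped with a warning, empty input is fine", {
  kb <- two_disease_kb()
  cases <- list(list(truth = "B1", evidence = ducg_evidence(c(X10 = 1))),
                list(evidence = ducg_evidence(c(X11 = 1))))
  expect_warning(report <- evaluate_batch(kb, cases), "unlabelled")
  expect_equal(report$totals$test_cases, 1)
  empty <- evaluate_batch(kb, list())
  expect_equal(empty$totals$test_cases, 0)
  expect_equal(empty$totals$accuracy, 0)
})

test_that("batch case files round-trip through read_case", {
  kb <- two_disease_kb()
  tmp <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    list(label = "one", truth = "B1", observations = list(X10 = 1L, X12 = 1L)),
    list(label = "two", truth = "B2", observations = list(X11 = 1L))), tmp)
  cases <- read_case(tmp, kb = kb)
  expect_length(cases, 2L)
  expect_identical(cases[[1]]$truth, "B1")
  expect_identical(cases[[2]]$evidence$observations, c(X11 = 1L))
  report <- evaluate_batch(kb, cases)
  expect_equal(report$totals$accuracy, 100)
})

test_that("the command-line front end diagnoses and validates", {
  script <- system.file("exec", "ducg", package = "ducgdx")
  expect_true(nzchar(script))
  kb_path <- system.file("extdata", "kb", "three_disease", package = "ducgdx")
  out <- system2("Rscript", c(script, "validate", kb_path),
                 stdout = TRUE, stderr = TRUE)
  expect_identical(attr(out, "status"), NULL)  # exit code 0
  expect_true(any(grepl("OK", out)))

  case_path <- system.file("extdata", "cases", "throat_consultation.yaml",
                           package = "ducgdx")
  out2 <- system2("Rscript", c(script, "diagnose", kb_path, case_path,
                               "--json"), stdout = TRUE, stderr = TRUE)
  parsed <- jsonlite::fromJSON(paste(out2, collapse = "\n"))
  expect_identical(parsed$disease[1], "B23")  # pH monitoring settles it
  expect_gt(parsed$posterior[1], 0.9)

  out3 <- system2("Rscript", c(script, "verify", kb_path, case_path,
                               "--cap", "60"), stdout = TRUE, stderr = TRUE)
  expect_identical(attr(out3, "status"), NULL)
})
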