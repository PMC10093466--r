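#' Diagnostic accuracy
#'
#' `100 * true_cases / test_cases`, the percentage of test cases whose
#' top-1 diagnosis matches the case record. A disease tested with zero
#' cases reports 0% with a warning.
#'
#' @param true_cases,test_cases Non-negative integers with
#'   `true_cases <= test_cases`.
#' @return Percentage in \[0, 100\].
#' @examples
#' accuracy(9, 10)   # 90
#' accuracy(10, 10)  # 100
#' @export
accuracy <- function(true_cases, test_cases) {
  stopifnot(true_cases >= 0, test_cases >= 0)
  if (true_cases > test_cases)
    stop("true_cases (", true_cases, ") exceeds test_cases (", test_cases, ")",
         call. = FALSE)
  if (test_cases == 0) {
    warning("no test cases; accuracy reported as 0%", call. = FALSE)
    return(0)
  }
  100 * true_cases / test_cases
}

#' Batch evaluation of the diagnostic engine
#'
#' Runs [diagnose()] on a list of gold-labelled cases and scores top-1
#' accuracy per disease and overall. The top-ranked disease is regarded as
#' the system's diagnostic result; a case is true when it matches the gold
#' label.
#'
#' @param kb A `ducg`.
#' @param cases List of `list(truth, evidence, label?)` entries (as
#'   produced by [sample_cases()] or [read_case()] on a batch file).
#' @param leak Isolated-evidence leak probability.
#' @return A `ducg_eval_report`: list with `per_disease` (data frame of
#'   test cases, true cases and accuracy % per disease), `totals`, and
#'   `misdiagnoses` (case id, truth, predicted). Unlabelled cases are
#'   skipped with a warning.
#' @export
evaluate_batch <- function(kb, cases, leak = 0.01) {
  labelled <- vapply(cases, function(cs) !is.null(cs$truth), logical(1))
  if (any(!labelled))
    warning(sum(!labelled), " unlabelled case(s) skipped", call. = FALSE)
  cases <- cases[labelled]
  truths <- vapply(cases, function(cs) cs$truth, character(1))
  predicted <- vapply(cases, function(cs) {
    res <- diagnose(kb, cs$evidence, leak = leak)
    if (nrow(res) == 0L) NA_character_ else res$disease[1]
  }, character(1))

  diseases <- sort(unique(c(truths, disease_ids(kb))))
  diseases <- diseases[order_ids(diseases)]
  per_disease <- do.call(rbind, lapply(diseases, function(d) {
    idx <- truths == d
    tested <- sum(idx)
    true_n <- sum(idx & !is.na(predicted) & predicted == d)
    data.frame(disease = d,
               label = kb$variables[[d]]$label %||% "",
               test_cases = tested, true_cases = true_n,
               accuracy = if (tested == 0) 0 else 100 * true_n / tested,
               stringsAsFactors = FALSE)
  }))
  rownames(per_disease) <- NULL
  total_test <- sum(per_disease$test_cases)
  total_true <- sum(per_disease$true_cases)
  wrong <- which(is.na(predicted) | predicted != truths)
  misdiagnoses <- data.frame(
    case = wrong,
    truth = truths[wrong],
    predicted = predicted[wrong],
    stringsAsFactors = FALSE)
  structure(list(
    per_disease = per_disease,
    totals = data.frame(test_cases = total_test, true_cases = total_true,
                        accuracy = if (total_test == 0) 0 else
                          100 * total_true / total_test),
    misdiagnoses = misdiagnoses), class = "ducg_eval_report")
}

#' @export
print.ducg_eval_report <- function(x, ...) {
  df <- x$per_disease
  df$accuracy <- sprintf("%.1f%%", df$accuracy)
  print.data.frame(df, row.names = FALSE)
  cat(sprintf("total: %d/%d correct, accuracy %.2f%%\n",
              x$totals$true_cases, x$totals$test_cases, x$totals$accuracy))
  if (nrow(x$misdiagnoses) > 0L) {
    cat("misdiagnoses:\n")
    print.data.frame(x$misdiagnoses, row.names = FALSE)
  }
  invisible(x)
}

#' JSON rendering of an evaluation report
#'
#' @param report A `ducg_eval_report`.
#' @return JSON string; agrees field-for-field with the printed table.
#' @export
eval_report_json <- function(report) {
  jsonlite::toJSON(list(per_disease = report$per_disease,
                        totals = report$totals,
                        misdiagnoses = report$misdiagnoses),
                   dataframe = "rows", auto_unbox = TRUE, pretty = TRUE,
                   digits = NA)
}

#' Engine-versus-oracle verification
#'
#' Diagnoses the evidence with the chain-reasoning engine and recomputes
#' every hypothesis's joint probability with the brute-force enumeration
#' oracle, reporting the largest absolute discrepancy.
#'
#' @param kb A `ducg` small enough for enumeration.
#' @param ev Evidence.
#' @param leak Isolated-evidence leak probability.
#' @param cap Oracle size cap (see [enumerate_zeta()]).
#' @return List with `engine` (diagnosis), `oracle_zeta`, and
#'   `max_abs_diff`.
#' @export
verify_engine <- function(kb, ev, leak = 0.01, cap = 20L) {
  if (!inherits(ev, "ducg_evidence")) ev <- ducg_evidence(ev, kb = kb)
  res <- diagnose(kb, ev, leak = leak)
  views <- attr(res, "views") %||% list()
  oracle <- vapply(views, enumerate_zeta, numeric(1), ev = ev, leak = leak,
                   cap = cap)
  names(oracle) <- vapply(views, function(v)
    paste0(v$disease, ",", v$state), character(1))
  engine <- setNames(res$zeta, paste0(res$disease, ",", res$state))
  keys <- names(oracle)
  list(engine = res, oracle_zeta = oracle,
       max_abs_diff = if (length(keys) == 0L) 0 else
         max(abs(engine[keys] - oracle[keys])))
}
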