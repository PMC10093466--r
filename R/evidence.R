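#' Patient evidence
#'
#' A case is a set of observed variable states. The observations are
#' partitioned into abnormal evidence E' (state != 0) and normal evidence
#' E'' (state 0); observations on risk-factor variables (parents of a
#' logic gate) form a third group consumed by the gate logic when
#' rescaling disease priors, rather than entering the causal likelihood.
#'
#' @param observations Named integer vector mapping variable id to
#'   observed state, e.g. `c(X21 = 1, X22 = 0)`.
#' @param kb Optional `ducg` to validate against: observed variables must
#'   exist, observed states must be in range, and disease roots (kinds B
#'   and BX) are never directly observable.
#' @return An object of class `ducg_evidence` with elements
#'   `observations`, `abnormal`, `normal`.
#' @examples
#' ev <- ducg_evidence(c(X21 = 1, X22 = 0), kb = three_disease_kb())
#' ev$abnormal
#' @export
ducg_evidence <- function(observations, kb = NULL) {
  if (length(observations) == 0L) {
    observations <- setNames(integer(0), character(0))
  } else {
    if (is.null(names(observations)) || any(!nzchar(names(observations))))
      stop("observations must be a named vector of states", call. = FALSE)
    if (anyDuplicated(names(observations)))
      stop("duplicate observation for ",
           names(observations)[duplicated(names(observations))][1],
           call. = FALSE)
    observations <- setNames(as.integer(observations), names(observations))
  }
  if (!is.null(kb)) {
    missing <- setdiff(names(observations), names(kb$variables))
    if (length(missing) > 0L)
      stop("evidence names variables absent from the knowledge base: ",
           paste(missing, collapse = ", "), call. = FALSE)
    for (id in names(observations)) {
      v <- kb$variables[[id]]
      if (v$kind %in% c("B", "BX"))
        stop("disease roots are not directly observable (", id, ")",
             call. = FALSE)
      if (observations[[id]] < 0L || observations[[id]] >= v$n_states)
        stop("observed state ", observations[[id]], " out of range for ", id,
             call. = FALSE)
    }
  }
  structure(list(
    observations = observations,
    abnormal = observations[observations != 0L],
    normal = observations[observations == 0L]
  ), class = "ducg_evidence")
}

#' @export
print.ducg_evidence <- function(x, ...) {
  fmt <- function(v) if (length(v) == 0L) "-" else
    paste(names(v), v, sep = ",", collapse = " ")
  cat("<evidence E' = ", fmt(x$abnormal), " | E'' = ", fmt(x$normal), ">\n",
      sep = "")
  invisible(x)
}

read_case_states <- function(doc) {
  obs <- doc$observations %||% doc
  obs <- obs[!names(obs) %in% c("label", "truth", "id")]
  setNames(as.integer(unlist(obs)), names(obs))
}

#' Read a patient case file
#'
#' A case file is a YAML or JSON mapping of variable id to observed state,
#' optionally wrapped as `{label: ..., truth: ..., observations: {...}}`.
#' A batch file is a list of such entries.
#'
#' @param path File path.
#' @param kb Optional `ducg` to validate observations against.
#' @return A `ducg_evidence` (single case) or a list of
#'   `list(label, truth, evidence)` entries (batch file).
#' @export
read_case <- function(path, kb = NULL) {
  doc <- read_kb_document(path)
  if (is.list(doc) && is.null(names(doc))) {
    return(lapply(seq_along(doc), function(i)
      list(label = doc[[i]]$label %||% paste0("case", i),
           truth = doc[[i]]$truth,
           evidence = ducg_evidence(read_case_states(doc[[i]]), kb = kb))))
  }
  ducg_evidence(read_case_states(doc), kb = kb)
}

# split observations into gate fodder vs causal-net evidence
split_risk_evidence <- function(kb, ev) {
  risky <- intersect(names(ev$observations), risk_factor_ids(kb))
  list(risk = ev$observations[risky],
       net = ducg_evidence(ev$observations[setdiff(names(ev$observations),
                                                   risky)]))
}
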