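# Risk-factor logic gates and prior rescaling.
#
# A disease's incidence can depend on anamnesis items (risk factors). The
# gate's logic specification table maps combinations of risk-factor states
# to gate states; the sa record then multiplies the disease prior by the
# factor attached to the realized gate state.

GATE_LITERAL_RE <- "[A-Za-z]+[0-9]+\\s*=\\s*[0-9]+"

# Parse a gate expression into an R call over state literals.
# Grammar: literals `X74=1`; operators ! & | and parentheses.
parse_gate_expr <- function(expr) {
  stopifnot(is.character(expr), length(expr) == 1L)
  stripped <- gsub(GATE_LITERAL_RE, "", expr)
  if (grepl("[^!&|() ]", stripped))
    stop("gate expression '", expr, "' contains unsupported tokens",
         call. = FALSE)
  translated <- gsub(paste0("([A-Za-z]+[0-9]+)\\s*=\\s*([0-9]+)"),
                     '(.states[["\\1"]] == \\2)', expr)
  str2lang(translated)
}

gate_expr_vars <- function(expr) {
  m <- gregexpr(GATE_LITERAL_RE, expr)[[1]]
  if (m[1] == -1) return(character(0))
  lits <- regmatches(expr, gregexpr(GATE_LITERAL_RE, expr))[[1]]
  unique(sub("\\s*=.*$", "", lits))
}

# Evaluate a gate under a named integer state assignment; unmentioned
# risk factors default to state 0 (elicited-or-assumed-absent convention).
evaluate_gate <- function(gate, states) {
  vars <- unique(unlist(lapply(gate$rows, function(row) gate_expr_vars(row$expr))))
  full <- setNames(rep(0L, length(vars)), vars)
  known <- intersect(names(states), vars)
  full[known] <- as.integer(states[known])
  env <- new.env(parent = baseenv())
  assign(".states", as.list(full), envir = env)
  for (row in gate$rows) {
    if (isTRUE(eval(parse_gate_expr(row$expr), env))) return(row$state)
  }
  gate$remnant
}

#' Risk-factor-adjusted prior of a disease
#'
#' Computes the prior of a disease's conditional root (its BX variable)
#' given the observed risk factors: the disease's logic gate is evaluated
#' on the risk-factor states (unobserved risk factors default to the
#' normal state 0), the multiplier attached to the realized gate state is
#' looked up in the sa record, and each abnormal state of the base prior
#' is scaled by that multiplier. The total abnormal mass is clipped at 1
#' (states are renormalized proportionally if the scaled total exceeds 1);
#' the normal state takes the residual mass.
#'
#' A disease with no gate/sa triple passes its raw prior through
#' unchanged.
#'
#' @param kb A `ducg` knowledge base.
#' @param disease Disease root id (kind `B`).
#' @param risk_evidence A [ducg_evidence()] object, or a named integer
#'   vector of observed states; only risk-factor variables are consulted.
#' @return Probability vector over the disease states (normal state
#'   first).
#' @examples
#' kb <- lpr_subducg()
#' compute_bx_prior(kb, "B23", c(X74 = 1))["1"]  # 10 x 0.03 = 0.3
#' compute_bx_prior(kb, "B23", c(X74 = 0))["1"]  # 0.03
#' @export
compute_bx_prior <- function(kb, disease, risk_evidence = NULL) {
  v <- kb$variables[[disease]]
  if (is.null(v) || v$kind != "B")
    stop("'", disease, "' is not a disease root of this knowledge base",
         call. = FALSE)
  prior <- setNames(v$prior, as.character(seq_len(v$n_states) - 1L))
  s <- kb$sa[[disease]]
  if (is.null(s)) return(prior)
  states <- if (inherits(risk_evidence, "ducg_evidence"))
    risk_evidence$observations else
      setNames(as.integer(risk_evidence), names(risk_evidence))
  gstate <- evaluate_gate(kb$gates[[s$gate]], states)
  f <- s$factors[gstate + 1L]
  if (is.na(f))
    stop("gate state ", gstate, " has no factor in the sa record of ",
         disease, call. = FALSE)
  abnormal <- prior[-1L] * f
  if (sum(abnormal) > 1) abnormal <- abnormal / sum(abnormal)
  c(setNames(1 - sum(abnormal), "0"), abnormal)
}
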