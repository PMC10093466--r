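---
title: "Chain reasoning over dynamic uncertain causality graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chain reasoning over dynamic uncertain causality graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ducgdx)
```

## The model

`ducgdx` implements differential diagnosis over a *dynamic uncertain
causality graph* (DUCG): a directed acyclic graphical model in which
root-cause variables (diseases, `B`) cause consequence variables
(symptoms, signs, test results, `X`/`SX`) through *weighted functional
events*. A link from parent $V_i$ to child $X_n$ carries a causal
intensity $r_{n;i} > 0$ and a strength matrix $a_{nk;ij} \in [0,1]$; the
child's state distribution given its parents' states $j_i$ is the
r-weighted mixture

$$\Pr\{X_n = k \mid \mathrm{pa}\} \;=\; \sum_i \frac{r_{n;i}}{r_n}\,
a_{nk;ij_i}, \qquad r_n = \sum_i r_{n;i},\; k \ge 1,$$

with the residual mass on the normal state $k = 0$. The weighting makes
each parent's influence a share of a unit budget, so a convex set of
single-cause mechanisms rather than a full conditional probability table
has to be elicited — the reason this representation suits knowledge
engineering with clinicians, who can state "this disease causes this
sign with strength $a$" without ever enumerating joint parent
configurations. State 0 of every variable is its normal state, and a
normal parent state causes nothing unless explicitly authored.

Each disease is modelled as an independent single-disease module
(sub-DUCG) and the modules are merged mechanically: variables with the
same id unify, and a manifestation shared by several diseases collects
the union of their incoming links (`merge_subgraphs()`, order
independent). This keeps a large knowledge base maintainable — editing
one disease never touches another module.

### Risk factors

A disease's incidence can depend on anamnesis items. A logic gate (`SG`)
maps combinations of risk-factor states to gate states through an
ordered specification table with a remnant (default) row; an `SA` record
attaches a non-negative multiplier to each gate state, and the
conditional root (`BX`) takes the base prior rescaled by the realized
multiplier (`compute_bx_prior()`). The remnant multiplier is pinned to 1
so an absent risk factor leaves the prior unchanged. In the packaged
laryngopharyngeal-reflux module the base abnormal prior is 0.03 and a
history of reflux esophagitis multiplies it by 10, giving 0.3.

Three conventions are ours where the source material is silent:
unobserved risk factors are treated as absent (state 0) when a gate is
evaluated, matching how anamnesis is either elicited or assumed
negative; gate rows evaluate first-match-wins, which only matters for
tables with overlapping rows; and the rescaled abnormal mass is clipped
at 1 (proportionally renormalized for multi-state diseases) because a
multiplier can otherwise push a probability past 1.

Observations on risk-factor variables are consumed by gate logic only:
they rescale priors and are excluded from the evidence likelihood. The
alternative — treating an observed risk factor as abnormal evidence to
be causally explained — would penalize every disease that does not cause
it, which inverts their intended role as incidence modifiers.

## The four reasoning steps

`diagnose()` composes four stages.

**Simplification** (`simplify()`) deletes what the current evidence
makes irrelevant: barren variables (unobserved, no observed descendant),
diseases with no causal path to any abnormal finding, and — when a
parent state implies an abnormal child state with certainty but the
child is observed normal — the contradicted parent states. Weights
renormalize implicitly over surviving parents because $r_n$ is always
the sum over current parents. Additional simplification rules exist in
the wider DUCG literature; only the three derivable from the reasoning
semantics implemented here are applied.

**Decomposition** (`decompose()`) applies the single-fault premise: all
abnormal evidence is attributed to one root cause at a time. Every
abnormal state of every surviving disease becomes a hypothesis
$H_{kj}$, evaluated in a view where all other diseases are fixed normal.
Co-morbidity (multi-fault hypotheses) is out of scope.

**Evaluation** (`evaluate()`) computes the joint probability
$\zeta_{kj} = \Pr\{H_{kj}, E\}$ under the generative semantics above:
the hypothesis root contributes its (risk-adjusted) prior mass,
consequence variables follow the mixture distribution, and unobserved
intermediates are marginalized exactly by enumeration over the
ancestors of the evidence. Two evidence effects need conventions:

* *Negative evidence.* A normal observation on a manifestation the
  hypothesis can cause contributes its residual normal-state mass — a
  factor $\le 1$ that depresses $\zeta$. This is exact in the generative
  semantics.
* *Isolated evidence.* An abnormal observation with no causal path from
  the hypothesis would force $\zeta = 0$; instead it contributes a
  configurable leak probability (default 0.01) standing for an
  unmodelled default cause, so one stray finding weakens but does not
  annihilate a hypothesis. When explicit default-cause (`D`) roots are
  present, evidence they can reach is marginalized through them rather
  than leaked.

**Posterior** (`posterior()`) normalizes
$h_{kj} = \zeta_{kj} / \sum \zeta$ and ranks descending, ties broken by
ascending variable index so output is reproducible. If every $\zeta$ is
zero the result is an empty ranking flagged "no hypothesis explains the
evidence" rather than a division by zero.

The symbolic side of the algorithm — recursive expansion of an observed
event into a sum of products of root events and functional events with
state exclusion and absorption — is exposed by `expand()` and
`sop_probability()`. The expansion is the explanatory artefact (it shows
*which* chains carry the probability); the numeric $\zeta$ of record
comes from the exact marginalization, because a product of per-evidence
expansions is a sum of non-disjoint terms on converging structures.

### Verification against a brute-force oracle

`enumerate_zeta()` recomputes $\zeta$ by enumerating complete worlds at
the causal-mechanism level: for every child a parent-selection variable
(parent $i$ with probability $r_{n;i}/r_n$) and the selected mechanism's
outcome (state $k$ with probability $a_{nk;ij}$, residual to normal).
This makes the mixture semantics explicit and shares none of the
engine's shortcuts; it refuses graphs above a configurable atomic-event
cap (root states plus functional events, default 20) rather than
truncating. The test suite checks engine-versus-oracle agreement to
$10^{-9}$ on all packaged fixtures and on 100 seeded random graphs with
at most 12 atomic events, under both full and partial observation.

### Next-question selection

The consultation loop needs a "what should I ask next". The mechanism
implemented is one-step value of information: each unobserved
manifestation is scored by the expected reduction in posterior entropy
over its states, with outcome probabilities from the current posterior
mixture and per-hypothesis conditionals renormalized over states (the
leak convention makes the raw conditionals slightly improper). This is
our design choice — any myopic acquisition criterion would fit the
interface — and it is deterministic, with ties broken by variable
index. Suggestions stop once the top posterior exceeds a confirmation
threshold (default 0.99).

### Gold standards

`SX` variables mark manifestations that clinically confirm one disease.
They participate in inference as ordinary high-specificity links; when
one is observed abnormal the affected disease is flagged
"gold-standard confirmed" in the result, but its posterior is still the
computed one — no hard override, since even confirmatory evidence is
displayed as a probability in this framework.

## What the fixtures emulate

The packaged laryngopharyngeal reflux module carries the published
prior (abnormal mass 0.03), the reflux-esophagitis gate with its 10×
multiplier, and the proton-pump-inhibitor gold standard. Its causal
strengths, however, are synthetic: the full clinical knowledge base
(354 variables, 651 functional events) is not publicly available, so
strengths were fixed once at clinically plausible values and committed.
The three-disease graph (chronic laryngitis 0.04, chronic pharyngitis
0.09, reflux 0.03, overlapping throat symptoms) reproduces the *shape*
of a staged consultation — a broad differential from symptoms alone,
narrowed by a laryngoscopy finding, settled by pH monitoring — not any
published posterior. The 27-disease skeleton carries the full disease
roster (with its index gap: there is no B21) and placeholder structure
only. Passing tests on these fixtures demonstrates the reasoning
machinery, not the clinical accuracy of the deployed system, which
depends entirely on the elicited parameters.

`random_kb()` generates two-layer disease/manifestation graphs with
exclusive "distinguishing" links and shared background links;
`sample_cases()` forward-samples single-fault worlds from the generative
semantics, so engine accuracy on them is a self-consistency check. Real
cases differ in ways these generators deliberately do not model:
co-morbidity, reporting noise, missingness correlated with severity,
and deeper causal chains.

## Numerical and scale choices

Probability comparisons use an absolute tolerance of $10^{-9}$;
priors must sum to 1 within $10^{-12}$. The validator's overflow check
(can any joint parent configuration push a child's abnormal mass past
1?) exploits separability of the mixture across parents, so it is exact
without enumerating joint configurations. Problem sizes in the test
suite were chosen to keep the whole suite around half a minute on one
core: oracle cross-checks use graphs of at most 12 atomic events (the
enumeration is exponential by design), and the self-consistency
simulation uses 5 diseases × 20 manifestations × 500 sampled cases,
which recovers the generating disease in well over 90% of cases when
each disease has three distinguishing links of strength ≥ 0.8 at leak
0.01.

## Known limitations

* Causal loops and continuous/fuzzy evidence — capabilities of the
  wider DUCG family — are not implemented; graphs must be acyclic and
  evidence discrete.
* Single-fault only: the engine never entertains joint multi-disease
  hypotheses. Sequential consultation is supported by re-running
  `diagnose()` with accumulated evidence.
* `RG`-type parents appear in the general DUCG taxonomy but are not
  supported; the loader flags them.
* Exact marginalization enumerates unobserved-ancestor states, which is
  exponential in the number of unobserved intermediates; fine for
  knowledge bases where evidence lands on or near the observed leaves,
  not for deeply hidden structure.
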