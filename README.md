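# ducgdx

Differential diagnosis by chain reasoning over **dynamic uncertain
causality graphs** (DUCG) — a probabilistic graphical model built for
clinical knowledge engineering, where each disease is authored as an
independent causal module and merged mechanically into one diagnostic
knowledge base. The package is aimed at clinical decision-support
developers and at anyone studying causal diagnostic inference with
weighted functional events: it provides the knowledge-base format and
validator, the inference engine, a brute-force verification oracle,
per-hypothesis graphical explanation, and a batch accuracy harness.

## The model in brief

A DUCG is a DAG of multi-state variables (state 0 = normal). Diseases
are root causes `B` with prior distributions; symptoms, signs and tests
are consequences `X` (or `SX` for clinical gold standards). A causal
link carries an intensity `r` and a strength matrix `a`, and a child's
state distribution is the r-weighted mixture

    Pr(X_n = k | parents) = Σ_i (r_i / Σ r) · a[k, j_i],   k ≥ 1,

with the residual mass on the normal state. Risk factors act through
logic gates: an ordered specification table maps risk-factor state
combinations to gate states, each of which multiplies the disease prior
(so a history of reflux esophagitis, say, can raise a 0.03 prior to
0.3). Inference runs in four steps — evidence-driven simplification,
single-fault decomposition, evaluation of ζ = Pr(hypothesis ∧ evidence),
and posterior normalization h = ζ / Σ ζ — and every hypothesis comes
with a graph-structural explanation of which findings it explains, which
it cannot (isolated evidence, charged a leak factor), and which normal
findings count against it.

## Worked example

The packaged three-disease knowledge base (chronic laryngitis, chronic
pharyngitis, laryngopharyngeal reflux with priors 0.04 / 0.09 / 0.03 and
overlapping throat symptoms) diagnosing a staged consultation:

```r
library(ducgdx)
kb <- three_disease_kb()

# presenting symptoms: sore throat, hoarseness, foreign-body sensation,
# itching, throat clearing; no dry throat / cough / expectoration;
# young male in the subacute stage (risk factors)
ev <- c(X85 = 1, X21 = 1, X45 = 1, X44 = 1, X150 = 1,
        X5 = 1, X52 = 1, X7 = 4, X51 = 0, X22 = 0, X23 = 0)
diagnose(kb, ev)
#>  hypothesis                    label      zeta posterior gold
#>       B12,1      Chronic pharyngitis 3.544e-06    80.63%
#>       B11,1       Chronic laryngitis 6.067e-07    13.80%
#>       B23,1 Laryngopharyngeal reflux 2.444e-07     5.56%
```

`zeta` is the joint probability of the hypothesis with all observations;
`posterior` is its share after normalization. The differential is broad,
so ask what discriminates best (one-step value of information):

```r
suggest_next(kb, ev)
#>       variable                                label       gain
#> SX160    SX160 Proton pump inhibitors are effective 0.15479973
#> X158      X158    Pharyngeal pH monitoring positive 0.10700003
#> X153      X153                     Vocal cord edema 0.03895778
```

Adding the laryngoscopy finding and a positive pH monitoring settles it:

```r
diagnose(kb, c(ev, X153 = 1, X158 = 1))
#>  hypothesis                    label      zeta posterior gold
#>       B23,1 Laryngopharyngeal reflux 3.850e-08    96.82%
#>       B11,1       Chronic laryngitis 9.100e-10     2.29%
#>       B12,1      Chronic pharyngitis 3.544e-10     0.89%
```

Each hypothesis carries its explanation (also exportable as Graphviz
DOT via `render_interpretation(..., format = "DOT")`):

```r
cat(render_interpretation(attr(diagnose(kb, ev), "interpretations")[[1]]))
#> hypothesis B11,1 (root BX11)
#> explained abnormal evidence:
#>   X85 = 1
#>   X21 = 1
#>   X45 = 1
#>   X44 = 1
#> isolated abnormal evidence:
#>   X150 = 1
#> ...
```

Chronic laryngitis explains most abnormal findings but not throat
clearing (`X150`), which is therefore isolated under that hypothesis and
costs it a leak factor.

Knowledge bases live in a declarative YAML/JSON dialect
(`load_kb()` / `write_kb()`, one file per disease module plus an index,
see `inst/extdata/kb/`), and a thin command-line front end wraps the
same functions:

```sh
ducg validate inst/extdata/kb/three_disease
ducg diagnose inst/extdata/kb/three_disease inst/extdata/cases/throat_consultation.yaml --json
ducg verify   inst/extdata/kb/three_disease inst/extdata/cases/throat_consultation.yaml --cap 60
```

Engine correctness is verified against `enumerate_zeta()`, a deliberately
naive oracle that enumerates complete causal-mechanism worlds on small
graphs; see the methods vignette (`vignettes/ducg-methods.Rmd`) for the
semantics, conventions and their rationale.

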