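Package: ducgdx
Title: Dynamic Uncertain Causality Graph Engine for Differential Diagnosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Knowledge representation and chain-reasoning inference for
    Dynamic Uncertain Causality Graphs (DUCG), a probabilistic graphical
    model for differential diagnosis of a chief complaint. Provides a
    declarative YAML/JSON knowledge-base format with validation and
    modular sub-graph merging, risk-factor logic gates that rescale
    disease priors, the four-step chain-reasoning algorithm (evidence
    driven simplification, single-fault decomposition, symbolic
    sum-of-products expansion, posterior computation), per-hypothesis
    graphical explanation with DOT export, a brute-force exact
    enumeration oracle for engine verification, packaged fixture
    knowledge bases with seeded random generators, and a batch accuracy
    evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
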