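Package: rewritask
Title: String-Rewriting Problem-Solving Tasks, State-Value Heuristics, and
    Transfer-of-Learning Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying transfer of learning between string
    transformation (rewriting) problem-solving tasks. Provides an exact
    task engine with bounded state-space enumeration, a difficulty-controlled
    generator of non-isomorphic rulesets and balanced tasksets, a parametric
    logistic state-value heuristic over 13 string features with
    cross-validated cross-taskset transfer evaluation, behavioural
    performance measures computed from timestamped event logs (solution
    rates, between-rule times, action-sequence efficiency, strategy-report
    weights, running-span working-memory scores, cursor speeds, exclusion
    filters), a synthetic participant simulator with associative and
    heuristic-search agents, and participant-level bootstrap inference
    including a probe-versus-training learning-rate contrast.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
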