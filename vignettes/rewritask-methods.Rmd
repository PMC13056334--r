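---
title: "Methods: string-rewriting tasks, state-value heuristics, and transfer analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: string-rewriting tasks, state-value heuristics, and transfer analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rewritask)
```

# The task formalism

A transformation problem presents a *state string* and a *goal string* over
a small symbol alphabet, plus a ruleset of rewrite rules `lhs -> rhs`.
Clicking a rule and a position in the state (in either order) attempts to
replace the substring starting at that position, of the same length as
`lhs`, by `rhs`; a mismatch is an *invalid application* that leaves the
state unchanged. A solution is any application sequence transforming the
start into the goal. Positions are 0-based throughout, mirroring the
click-on-a-symbol interaction: a rule fits only if
`position + nchar(lhs) <= nchar(state)`.

`state_graph()` enumerates all states reachable from the start by
breadth-first search and computes every state's distance to the goal by a
reverse breadth-first search over the enumerated edges. Rewriting systems
can grow without bound, so enumeration is always bounded by explicit caps
(`graph_caps()`: depth, string length, node count) and the graph records
whether any cap bound the search. Downstream consumers treat a truncated
graph as unusable rather than silently approximate: the task generator
rejects truncated starts and `label_reachability()` raises an error.

Degenerate conventions, chosen once and used consistently: a task whose
start equals its goal has one (empty) minimal solution; an unreachable
goal is represented with distance infinity; the goal string is present in
the graph even when unreachable so that `distance(goal) = 0` always holds.

# Difficulty criteria and the task generator

Study-grade tasksets contain 72 tasks, 24 at each minimal solution length
4, 5, and 6, every task satisfying:

* between two and four distinct minimal solution sequences (two sequences
  are distinct if they differ in rule, position, or any intermediate
  state);
* goal length at least three symbols;
* a "wrong turn" available at every state on a minimal solution path —
  i.e. each such state has at least one successor that is *not* on any
  minimal path from it (a successor whose distance is not one less);
* no commutative transition: no state reachable from a common ancestor by
  the *same two* (rule, position) applications in either order;
* unique (start, goal) pairs.

`count_minimal_solutions()` counts minimal-length sequences by dynamic
programming over distance levels; a configuration switch
(`minimal_only = FALSE`) counts all acyclic solutions up to a length cap
instead, since "distinct solutions" admits both readings.

**Rule shapes.** The generator's default structural profile
(`structure_spec()`) uses five strictly shrinking rules: four of shape
`2 -> 1` and one `3 -> 2`. This choice is load-bearing in two ways. First,
with length-preserving rules, any two applications at non-overlapping
positions commute as literally the same (rule, position) pairs, so almost
every candidate task contains a commutative transition and the generator
starves. Length-changing rules shift the downstream position when order is
swapped, so the two orders are no longer the same application pair.
Second, strictly shrinking rules make every reachable state space finite
(strings never grow), so full enumeration within the caps always
terminates and tasks never have to be rejected for truncation. Minimal
solution length then equals `nchar(start) - nchar(goal)`; start strings
are sampled at lengths 7–10 so that goals of length ≥ 3 exist at depths
4–6.

Generation is rejection sampling made efficient by enumerating each
candidate start once and harvesting several goals from the same graph
(goals are chosen among enumerated states at the target depth, which
guarantees solvability and the exact minimal length). Commutativity is
checked once per start — it depends only on the reachable edge set, not
the goal. At most three tasks are taken per start so start states stay
diverse. Failure is loud: an attempt budget exhausts with an error, and
`generate_study_tasksets()` simply redraws the ruleset pair when one of
its rulesets cannot populate a length bucket (some random rulesets
cannot). `verify_task()` independently re-enumerates and re-checks every
criterion and is used as the acceptance oracle for generated materials.

# The state-value heuristic

The heuristic scores a (state, goal) pair as
`v(s, g) = expit(b0 + sum_i b_i f_i(s, g))` with thirteen string features:
positional match proportion (f1), length difference (f2), unique-symbol
count difference (f3), LCS length as a proportion of goal length (f4),
state/goal lengths (f5/f6), longest runs (f7/f8), shortest runs (f9/f10),
run-collapsed lengths (f11/f12), and Levenshtein distance (f13). Two
conventions the feature definitions leave open: f1's denominator is the
*state* length, with positions beyond the shorter string counted as
mismatches; and a lone symbol is a run of length 1, so shortest-run
features are typically 1.

Ground truth is binary reachability: for every task, every enumerated
state is labelled 1 if the task's goal is reachable from it and 0
otherwise, de-duplicating on (state, goal) across tasks. Evaluation sets
are class-balanced samples (400 of each label in study emulation), so the
0.5 classification threshold is canonical and chance is 0.50.

`evaluate_transfer()` runs stratified k-fold cross-validation (30 folds in
study emulation): each fold's model is fitted by unpenalised maximum
likelihood on the remaining folds, scored on the held-out fold (test
accuracy) and on the *entire* second taskset's evaluation set
(generalisation accuracy); medians and quartiles across folds are
reported. Perfect separation triggers a refit with a tiny ridge penalty
(1e-6) and a flag on the report. Per-fold Wald tests at the 1% level
feed the report's list of coefficients significant in *all* folds.
Feature ablations use only goal information (f6, f8, f10, f12) or only
state information (f5, f7, f9, f11).

On generator-produced materials the qualitative pattern is: the full model
generalises across tasksets well above chance, the state-only model sits
between, and the goal-only model is near 0.5. Exact accuracy levels depend
on the rulesets; the package makes no claim to reproduce any particular
taskset's numbers without those materials.

# Behavioural measures

All measures are computed from timestamped event logs (JSON-Lines; one
trial per line).

* **Attempts** are maximal rule-activation + symbol-activation pairs in
  either order; validity is read from whether a state change immediately
  follows. Two same-kind activations in a row discard the earlier one with
  a warning.
* **Between-rule time** defaults to the *gap* convention — the start of
  attempt k+1 minus the end of attempt k, i.e. idle/decision time between
  completed attempts. The phrase "difference between the end of one pair
  and the next pair" also admits end-to-end differencing, available via
  `mode = "end_to_end"`.
* **Action-sequence efficiency** comes in two modes that must not be
  conflated. `minimal_distance` (used for optimality-by-distance curves)
  considers solved trials only and asks whether the remaining number of
  successful applications from each visited state equals that state's
  minimal distance. `median_group` groups states by the median length of
  all acyclic solution paths from them (capped at distance + 6, since the
  uncapped set is infinite in general), counts every attempt including
  invalid ones while ignoring undo/reset, and scores unsolved trials as
  failures in every group they touch.
* **Strategy weights** convert the three pairwise preference proportions
  with `w_t = xy/(1-x+xy)`, `w_w = w_t(1-x)/x`, `w_i = w_w(1-y)/y`; the
  identity `w_t + w_w + w_i = 1` holds algebraically. The third preference
  `z` does not enter the formulae and is retained only as a consistency
  input. Extreme inputs (0 or 1) are clamped to 0.01/0.99 with a warning.
* **Working-memory score**: typed responses are right-aligned against the
  sequence tail (the alignment of free-typed responses is otherwise
  undefined); a logistic regression of correctness on offset is solved for
  the offset where recall crosses chance (1/9, digits 1–9), and the score
  is that crossing clamped to the observed offset range, plus one.
  Degenerate fits are flagged: non-decreasing recall or all-correct score
  at the ceiling, all-wrong at 1.
* **Exclusions**: a participant is dropped unless every session has at
  least one solved trial and an above-chance fitted recall probability at
  offset 0.
* **Cursor speed**: straight-line distance between the two click
  coordinates of an attempt divided by the time between them; zero time
  deltas are skipped with a warning.
* Block codes for regression tables: training blocks 2–7, probe blocks 0
  (pre) and 1 (post).

# The synthetic cohort

The simulator exists to make the pipeline testable end to end and to
realise the two competing mechanism regimes; it is a stand-in, not a model
fitted to human data.

Agents choose (rule, position) actions by softmax over mechanism-specific
utilities, slip into a random invalid application with a small probability
(0.06), click reset at dead ends, and avoid immediately undoing their last
transformation. Decision times are log-normal with a location that
declines linearly with cumulative attempts (0.0003 per attempt, floored),
spreading the practice speed-up over all four sessions; click coordinates
come from a fixed screen layout plus noise, so cursor-speed measures are
exercised. Trials truncate at 75 s.

**Heuristic-search agents** score candidate successors with the logistic
state-value heuristic. They learn by accumulating (visited state, goal,
reachability) labels and refitting the 14 coefficients between blocks with
a small ridge penalty, class-balanced, then shrinking the fit toward the
naive zero prior in proportion to evidence (`n/(n + 600)`). The shrinkage
makes skill consolidate gradually rather than after a single block, which
is what the study-like learning curves require; a raw per-trial stochastic
update on unscaled features was unstable and is not used. With transfer
enabled, coefficients and training samples are shared across rulesets —
the post-training probe then benefits from all prior training; with
transfer disabled each ruleset learns from scratch. An oracle mode
(`value_source = "oracle"`) scores successors by true negative distance
and is used for upper-bound checks only.

**Associative agents** learn strengths of pattern-action associations that
are keyed by rule identity — hence structurally unable to transfer to a
ruleset with different rules — but abstract across tasks of the same
ruleset: the rule alone, the rule with its local flanking symbols, the
rule with goal-relational bits (does its lhs/rhs occur in the goal; does
the move conserve the goal's symbol counts), and exact
(state, goal, action) memory. Updates are advantage-style delta rules: a
pattern's strength moves by (segment outcome − running success baseline),
where a segment is the stretch of trajectory between resets and its
outcome is whether it ended at the goal. Patterns used on above-average
segments drift positive, below-average ones negative, and unexplored
patterns stay at the average — a plain delta rule toward raw outcomes
fails here because feedback is failure-dominated early on.

A naive agent (zero coefficients, or empty associations) solves roughly
10–25% of generated 4–6-step tasks within 75 s, matching the intended
baseline regime. The working-memory simulator draws recall by offset from
a logistic curve with the agent's capacity as midpoint and types a
tail-aligned response. Strategy reports are produced by perturbing the
agent's strategy bias and encoding the weights back through the pairwise
preference formulae, so the conversion round-trip is exercised.

What the simulator does *not* emulate: undo-based exploration (agents only
reset), boredom/frustration dynamics, within-trial strategy switching,
device differences in cursor speed, and any fit to the human dataset.
Passing end-to-end tests therefore shows that the analysis pipeline
discriminates the two mechanism regimes under these idealised agents — not
that human data would behave identically.

# Inference

`bootstrap_diff_test()` is a participant-level percentile bootstrap: the
two-sided p is `2 * min(P(diff* <= 0), P(diff* >= 0))` over the resampled
difference distribution. Two standard corrections are applied: the
resampled statistics are rescaled about the observed value by
`sqrt(n/(n-1))` (the bootstrap distribution of a mean is narrower than the
sampling distribution by (n−1)/n), and the observed sample counts as one
resample (`(k+1)/(B+1)`). Defaults: 10,000 resamples; the resample count
is a config choice, not a prescribed value.

`learning_rate_contrast()` is a deliberately simple two-stage surrogate
for trial-level hierarchical modelling (which is out of scope here): per
participant and condition, a logistic slope of success on cumulative trial
number (ridge-penalised and flagged for all-success/all-failure cells),
then a participant-level bootstrap percentile interval for the mean
probe-minus-training slope difference. Hooks for external hierarchical
fitting are the tidy tables from `build_block_table()` and the raw trial
logs.

`transfer_analysis()` operationalises the headline question: the
per-participant change in solved proportion across the probe blocks
(p2 − p1) is compared with the change across the first two training
blocks (t2 − t1) by a paired bootstrap test; the cohort is flagged as
showing transfer when the probe change significantly exceeds the training
change.

# Problem sizes and numerical choices

The shipped tests run at study scale where the analysis is cheap
(72-task tasksets, 400/400 samples, 30 folds, 10 generator seeds, 2,000
null replications for calibration, cohorts of 30 agents) and at reduced
scale where only mechanics are being exercised (24-task tasksets for
simulator unit tests; the trial schedule recycles the task permutation
when a taskset is smaller than the 72-trial plan, a reduced-size emulation
mode that study-scale runs never enter). Enumeration caps in
generation/labelling default to depth 40 and 4,000 nodes — far above what
shrinking rulesets reach, so they act as safety rails, not approximations.
Stratified fold assignment, all sampling, and all simulators are driven by
explicit seeds; identical seeds give byte-identical datasets.

# Known limitations

* Accuracy levels of the transfer analysis depend on the generated
  rulesets; only the qualitative structure (full > state-only >
  goal-only ≈ chance; test ≈ generalisation) is a stable property.
* The associative and heuristic learning rules are defensible stand-ins
  chosen for stability and transparency; many alternatives exist in the
  mechanism literature.
* `median_remaining_solution_length()` enumerates acyclic paths and is
  exponential without its cap; the default cap (distance + 6) keeps it
  tractable on task-sized graphs but it is not intended for arbitrary
  large graphs.
* The bootstrap's small-sample rescaling is exact for means and an
  approximation for medians.
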