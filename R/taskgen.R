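#' Difficulty specification for task selection
#'
#' The difficulty criteria a task must meet: every task must have
#' between `n_solutions_range[1]` and `n_solutions_range[2]` distinct
#' minimal solution sequences, a minimal solution length inside
#' `min_length_range`, a goal of at least `goal_min_length` symbols, a
#' wrong turn available at every state on a minimal solution path, and no
#' commutative transitions.
#'
#' @param n_solutions_range Integer interval, default `c(2, 4)`.
#' @param min_length_range Integer interval, default `c(4, 6)`.
#' @param goal_min_length Minimum goal length, default 3.
#' @param require_wrong_turns,forbid_commutative Logical flags, default TRUE.
#' @return A list of class `difficulty_spec`.
#' @export
difficulty_spec <- function(n_solutions_range = c(2L, 4L),
                            min_length_range = c(4L, 6L),
                            goal_min_length = 3L,
                            require_wrong_turns = TRUE,
                            forbid_commutative = TRUE) {
  stopifnot(length(n_solutions_range) == 2L, length(min_length_range) == 2L,
            n_solutions_range[1] <= n_solutions_range[2],
            min_length_range[1] <= min_length_range[2],
            goal_min_length >= 1L)
  structure(list(n_solutions_range = as.integer(n_solutions_range),
                 min_length_range = as.integer(min_length_range),
                 goal_min_length = as.integer(goal_min_length),
                 require_wrong_turns = isTRUE(require_wrong_turns),
                 forbid_commutative = isTRUE(forbid_commutative)),
            class = "difficulty_spec")
}

#' Structural specification for ruleset generation
#'
#' The two rulesets of a study pair share the same multiset of
#' `(nchar(lhs), nchar(rhs))` rule shapes but must not be isomorphic under
#' symbol relabelling. The default profile uses strictly shrinking rules
#' (four `2 -> 1` rules and one `3 -> 2` rule). Length-changing rules are
#' essential for the difficulty criteria: with length-preserving rules any
#' two applications at non-overlapping positions commute as identical
#' (rule, position) pairs, so almost no task would pass the
#' no-commutative-transition filter. Strictly shrinking rules additionally
#' keep every reachable state space finite.
#'
#' @param n_rules Number of rules, default 5.
#' @param profile Two-column matrix (or list of length-2 vectors) of
#'   `(lhs length, rhs length)` pairs, one row per rule.
#' @param alphabet_size Symbols available per ruleset, default 4.
#' @return A list of class `structure_spec`.
#' @export
structure_spec <- function(n_rules = 5L,
                           profile = list(c(2L, 1L), c(2L, 1L), c(2L, 1L),
                                          c(2L, 1L), c(3L, 2L)),
                           alphabet_size = 4L) {
  if (is.matrix(profile))
    profile <- lapply(seq_len(nrow(profile)), function(i) profile[i, ])
  if (length(profile) != n_rules)
    stopf("profile must contain one (|lhs|, |rhs|) pair per rule")
  structure(list(n_rules = as.integer(n_rules),
                 profile = lapply(profile, as.integer),
                 alphabet_size = as.integer(alphabet_size)),
            class = "structure_spec")
}

.random_symbol_string <- function(len, alphabet) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

.random_ruleset <- function(spec, alphabet, id) {
  repeat {
    lhs <- vapply(spec$profile, function(p)
      .random_symbol_string(p[1], alphabet), character(1))
    rhs <- vapply(spec$profile, function(p)
      .random_symbol_string(p[2], alphabet), character(1))
    if (any(lhs == rhs)) next            # identity rules are useless
    if (anyDuplicated(paste(lhs, rhs))) next
    # every alphabet symbol should occur somewhere so the alphabet is
    # effective, and at least one rule must consume a writable symbol
    syms <- unique(unlist(strsplit(c(lhs, rhs), "")))
    if (!setequal(syms, alphabet)) next
    return(ruleset(data.frame(id = seq_along(lhs), lhs = lhs, rhs = rhs),
                   id = id, alphabet = alphabet))
  }
}

#' Generate a non-isomorphic pair of rulesets
#'
#' Rejection-samples two rulesets with identical rule-shape profiles until
#' [rulesets_isomorphic()] returns FALSE. By default the two rulesets use
#' disjoint symbol alphabets, mirroring a design in which no transformation
#' rule carries over between tasksets.
#'
#' @param spec A [structure_spec()].
#' @param seed Integer seed for reproducibility (optional).
#' @param shared_alphabet Use one shared alphabet for both rulesets instead
#'   of disjoint ones.
#' @param max_attempts Rejection-sampling budget.
#' @return A list with elements `a` and `b`, both [ruleset()] objects.
#' @export
generate_ruleset_pair <- function(spec = structure_spec(), seed = NULL,
                                  shared_alphabet = FALSE,
                                  max_attempts = 1000L) {
  with_seed(seed, {
    pool <- c(LETTERS, letters)
    k <- spec$alphabet_size
    if (shared_alphabet) {
      alpha_a <- alpha_b <- pool[seq_len(k)]
    } else {
      alpha_a <- pool[seq_len(k)]
      alpha_b <- pool[k + seq_len(k)]
    }
    for (i in seq_len(max_attempts)) {
      a <- .random_ruleset(spec, alpha_a, id = "A")
      b <- .random_ruleset(spec, alpha_b, id = "B")
      if (!rulesets_isomorphic(a, b)) return(list(a = a, b = b))
    }
    stopf("ruleset generation exhausted after %d attempts", max_attempts)
  })
}

#' Generate a difficulty-balanced taskset
#'
#' Rejection-samples start strings, enumerates each start's reachable state
#' graph once, and harvests `(start, goal)` pairs whose goals sit at the
#' target minimal distances and that satisfy every difficulty criterion.
#' Truncated graphs are rejected outright. In study-emulation mode
#' (`n_per_length = 24` over lengths 4-6) this yields 72 unique tasks,
#' 24 per minimal solution length.
#'
#' @param ruleset A [ruleset()].
#' @param spec A [difficulty_spec()].
#' @param n_per_length Tasks required per minimal solution length.
#' @param seed Integer seed (optional).
#' @param start_lengths Range of start-string lengths sampled.
#' @param caps [graph_caps()] used for enumeration.
#' @param max_starts Budget of candidate start strings.
#' @param max_per_start Cap on tasks harvested from one start string, to
#'   keep start states diverse.
#' @param id Taskset label.
#' @return An object of class `taskset`: fields `id`, `ruleset`, `tasks`
#'   (data.frame `start`, `goal`, `min_solution_length`,
#'   `n_minimal_solutions`), `balance`.
#' @export
generate_taskset <- function(ruleset, spec = difficulty_spec(),
                             n_per_length = 24L, seed = NULL,
                             start_lengths = c(7L, 10L),
                             caps = graph_caps(max_depth = 40L,
                                               max_nodes = 4000L),
                             max_starts = 50000L, max_per_start = 3L,
                             id = paste0("taskset-", ruleset$id)) {
  lengths <- seq.int(spec$min_length_range[1], spec$min_length_range[2])
  with_seed(seed, {
    need <- setNames(rep(as.integer(n_per_length), length(lengths)),
                     lengths)
    got <- setNames(rep(0L, length(lengths)), lengths)
    rows <- list()
    seen_pair <- new.env(parent = emptyenv())
    seen_start <- new.env(parent = emptyenv())
    for (attempt in seq_len(max_starts)) {
      if (all(got >= need)) break
      # bail out early on rulesets that cannot populate some length bucket
      if (attempt == 4000L && any(got == 0L))
        stopf("taskset generation exhausted: no tasks of length %s after %d starts",
              paste(names(got)[got == 0L], collapse = ","), attempt)
      len <- sample(seq.int(start_lengths[1], start_lengths[2]), 1L)
      start <- .random_symbol_string(len, ruleset$alphabet)
      if (!is.null(seen_start[[start]])) next
      assign(start, TRUE, envir = seen_start)
      base <- state_graph(start, goal = start, ruleset, caps = caps)
      if (base$truncated) next
      # commutativity depends only on the reachable edge set, not the goal
      if (spec$forbid_commutative && has_commutative_transition(base)) next
      taken_here <- 0L
      cand_depth <- base$depth[base$depth %in% lengths &
                                 nchar(names(base$depth)) >=
                                 spec$goal_min_length]
      if (!length(cand_depth)) next
      for (goal in sample(names(cand_depth))) {
        L <- cand_depth[[goal]]
        if (got[[as.character(L)]] >= need[[as.character(L)]]) next
        if (taken_here >= max_per_start) break
        key <- paste(start, goal, sep = "\r")
        if (!is.null(seen_pair[[key]])) next
        g <- .with_goal(base, goal)
        if (g$dist[[start]] != L) next
        ns <- count_minimal_solutions(g)
        if (ns < spec$n_solutions_range[1] ||
            ns > spec$n_solutions_range[2]) next
        if (spec$require_wrong_turns && !wrong_turn_everywhere(g)) next
        assign(key, TRUE, envir = seen_pair)
        rows[[length(rows) + 1L]] <- data.frame(
          start = start, goal = goal, min_solution_length = L,
          n_minimal_solutions = ns, stringsAsFactors = FALSE)
        got[[as.character(L)]] <- got[[as.character(L)]] + 1L
        taken_here <- taken_here + 1L
      }
    }
    if (!all(got >= need))
      stopf("taskset generation exhausted: found %s of %s tasks per length",
            paste(got, collapse = "/"), paste(need, collapse = "/"))
    tasks <- do.call(rbind, rows)
    tasks <- tasks[order(tasks$min_solution_length, tasks$start,
                         tasks$goal), ]
    rownames(tasks) <- NULL
    structure(list(id = id, ruleset = ruleset, tasks = tasks,
                   balance = table(tasks$min_solution_length)),
              class = "taskset")
  })
}

# Re-target an enumerated graph at a different goal: the node and edge sets
# (reachable from start) are goal-independent; only distances change.
.with_goal <- function(graph, goal) {
  g <- graph
  g$goal <- goal
  gi <- match(goal, g$nodes)
  dist <- as.numeric(reverse_bfs_cpp(length(g$nodes), g$ef, g$et, gi))
  dist[is.na(dist)] <- Inf
  names(dist) <- g$nodes
  g$dist <- dist
  g$goal_unreachable <- FALSE
  g
}

#' @export
print.taskset <- function(x, ...) {
  cat(sprintf("taskset '%s': %d tasks on ruleset '%s'\n", x$id,
              nrow(x$tasks), x$ruleset$id))
  print(x$balance)
  invisible(x)
}

#' Generate a full study materials set: ruleset pair plus two tasksets
#'
#' Rejection-samples non-isomorphic ruleset pairs until both rulesets can
#' furnish a difficulty-balanced taskset (some random rulesets cannot
#' populate every minimal-length bucket; such pairs are discarded and a new
#' pair drawn). All sampling is driven by `seed`, so the same seed yields
#' the same materials.
#'
#' @param structure A [structure_spec()].
#' @param difficulty A [difficulty_spec()].
#' @param n_per_length Tasks per minimal solution length (study emulation:
#'   24, giving 72 tasks per taskset).
#' @param seed Integer seed.
#' @param max_pair_attempts Ruleset pairs tried before giving up.
#' @param ... Further arguments passed to [generate_taskset()].
#' @return List with `rulesets` (list `a`, `b`) and tasksets `a`, `b`.
#' @export
generate_study_tasksets <- function(structure = structure_spec(),
                                    difficulty = difficulty_spec(),
                                    n_per_length = 24L, seed = NULL,
                                    max_pair_attempts = 25L, ...) {
  with_seed(seed, {
    for (i in seq_len(max_pair_attempts)) {
      pair <- generate_ruleset_pair(structure)
      ts <- tryCatch(
        list(a = generate_taskset(pair$a, difficulty,
                                  n_per_length = n_per_length,
                                  max_starts = 20000L, ...),
             b = generate_taskset(pair$b, difficulty,
                                  n_per_length = n_per_length,
                                  max_starts = 20000L, ...)),
        error = function(e) NULL)
      if (!is.null(ts))
        return(list(rulesets = pair, a = ts$a, b = ts$b))
    }
    stopf("no viable ruleset pair found in %d attempts", max_pair_attempts)
  })
}

#' Independently verify a generated task
#'
#' Re-enumerates the task's state graph from scratch and re-checks every
#' difficulty criterion. Used as the acceptance oracle for the generator.
#'
#' @param start,goal Symbol strings of the task.
#' @param ruleset A [ruleset()].
#' @param spec A [difficulty_spec()].
#' @param expected_length The task's recorded minimal solution length
#'   (optional; checked when given).
#' @param caps [graph_caps()] for the re-enumeration.
#' @return TRUE when every criterion holds, otherwise a character vector of
#'   failed criteria.
#' @export
verify_task <- function(start, goal, ruleset, spec = difficulty_spec(),
                        expected_length = NULL,
                        caps = graph_caps(max_depth = 40L,
                                          max_nodes = 4000L)) {
  g <- state_graph(start, goal, ruleset, caps = caps)
  fails <- character(0)
  if (g$truncated) fails <- c(fails, "graph truncated")
  d <- g$dist[[start]]
  if (!is.finite(d)) return(c(fails, "goal unreachable"))
  if (nchar(goal) < spec$goal_min_length) fails <- c(fails, "goal too short")
  if (d < spec$min_length_range[1] || d > spec$min_length_range[2])
    fails <- c(fails, "minimal length out of range")
  if (!is.null(expected_length) && d != expected_length)
    fails <- c(fails, "recorded minimal length incorrect")
  ns <- count_minimal_solutions(g)
  if (ns < spec$n_solutions_range[1] || ns > spec$n_solutions_range[2])
    fails <- c(fails, "minimal solution count out of range")
  if (spec$forbid_commutative && has_commutative_transition(g))
    fails <- c(fails, "commutative transition present")
  if (spec$require_wrong_turns && !wrong_turn_everywhere(g))
    fails <- c(fails, "wrong-turn property fails")
  if (!length(fails)) TRUE else fails
}

#' Score a solved trial
#'
#' Ten times the remaining trial time divided by the number of steps taken,
#' rounded down to the nearest integer. Trials run for at most 75 seconds.
#'
#' @param remaining_time Seconds left on the trial clock, in `[0, 75]`.
#' @param steps Number of rule applications used (>= 1).
#' @return Non-negative integer score.
#' @examples
#' trial_score(30, 5)  # 60
#' @export
trial_score <- function(remaining_time, steps) {
  if (any(steps < 1L)) stopf("steps must be >= 1")
  if (any(remaining_time < 0 | remaining_time > 75))
    stopf("remaining_time must lie in [0, 75]")
  as.integer(floor(10 * remaining_time / steps))
}

#' Write a taskset to JSON
#'
#' Serialises the ruleset and task list:
#' `{"ruleset": {"id", "alphabet", "rules": [{"id","lhs","rhs"}]},
#'   "tasks": [{"start","goal","min_solution_length"}]}`.
#'
#' @param taskset A [generate_taskset()] result.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_taskset <- function(taskset, path) {
  obj <- list(
    id = taskset$id,
    ruleset = list(
      id = taskset$ruleset$id,
      alphabet = taskset$ruleset$alphabet,
      rules = data.frame(id = taskset$ruleset$ids,
                         lhs = taskset$ruleset$lhs,
                         rhs = taskset$ruleset$rhs)),
    tasks = taskset$tasks)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a taskset from JSON
#'
#' Reads the format written by [write_taskset()]; also usable to load
#' externally transcribed rulesets and tasks.
#'
#' @param path JSON file path.
#' @return A `taskset` object.
#' @export
read_taskset <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rs <- ruleset(obj$ruleset$rules, id = obj$ruleset$id,
                alphabet = obj$ruleset$alphabet)
  tasks <- obj$tasks
  tasks$min_solution_length <- as.integer(tasks$min_solution_length)
  structure(list(id = obj$id %||% paste0("taskset-", rs$id), ruleset = rs,
                 tasks = tasks,
                 balance = table(tasks$min_solution_length)),
            class = "taskset")
}
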