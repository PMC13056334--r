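# Independent brute-force oracles used to check the engine, plus shared
# fixtures. Everything here is deliberately written without reference to
# the package's own graph/BFS code paths.

# All valid (rule index, position) applications of `ruleset` on `state`,
# computed with apply_rule only.
bf_moves <- function(state, ruleset) {
  out <- list()
  for (r in seq_along(ruleset$ids)) {
    rl <- rule(ruleset$ids[r], ruleset$lhs[r], ruleset$rhs[r])
    for (p in 0:(nchar(state) - 1L)) {
      to <- apply_rule(state, rl, p)
      if (!is.na(to))
        out[[length(out) + 1L]] <- list(rule = ruleset$ids[r], pos = p,
                                        to = to)
    }
  }
  out
}

# Depth-first enumeration of action sequences from start, memoised on
# (state, remaining budget): the minimum number of applications reaching
# the goal within depth_cap, or Inf. Independent of the package's
# breadth-first graph construction.
bf_distance <- function(start, goal, ruleset, depth_cap = 6L) {
  memo <- new.env(parent = emptyenv())
  rec <- function(s, budget) {
    if (s == goal) return(0)
    if (budget == 0L) return(Inf)
    key <- paste(s, budget)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- Inf
    for (mv in bf_moves(s, ruleset)) {
      d <- rec(mv$to, budget - 1L)
      if (d + 1 < best) best <- d + 1
    }
    memo[[key]] <- best
    best
  }
  rec(start, as.integer(depth_cap))
}

# Number of distinct minimal action sequences (sequences of (rule, pos)),
# counted by depth-first enumeration memoised on (state, steps left).
bf_count_minimal <- function(start, goal, ruleset, depth_cap = 6L) {
  d <- bf_distance(start, goal, ruleset, depth_cap)
  if (is.infinite(d)) stop("goal unreachable")
  if (d == 0) return(1L)
  memo <- new.env(parent = emptyenv())
  rec <- function(s, k) {
    if (k == 0L) return(as.integer(s == goal))
    key <- paste(s, k)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    n <- 0L
    for (mv in bf_moves(s, ruleset)) n <- n + rec(mv$to, k - 1L)
    memo[[key]] <- n
    n
  }
  rec(start, as.integer(d))
}

# Brute-force scan for a commutative transition over all start-reachable
# states of a graph (an unreachable goal is present as an isolated node
# but is not part of the enumerated state space).
bf_commutative <- function(graph, ruleset) {
  for (s in graph$nodes[!is.na(graph$depth)]) {
    mvs <- bf_moves(s, ruleset)
    if (length(mvs) < 2L) next
    for (i in seq_along(mvs)) {
      for (j in seq_along(mvs)) {
        if (i == j) next
        m1 <- mvs[[i]]; m2 <- mvs[[j]]
        r1 <- rule(m1$rule, ruleset$lhs[match(m1$rule, ruleset$ids)],
                   ruleset$rhs[match(m1$rule, ruleset$ids)])
        r2 <- rule(m2$rule, ruleset$lhs[match(m2$rule, ruleset$ids)],
                   ruleset$rhs[match(m2$rule, ruleset$ids)])
        if (m2$pos > nchar(m1$to) - 1L) next
        w1 <- apply_rule(m1$to, r2, m2$pos)
        if (is.na(w1)) next
        if (m1$pos > nchar(m2$to) - 1L) next
        w2 <- apply_rule(m2$to, r1, m1$pos)
        if (!is.na(w2) && w1 == w2) return(TRUE)
      }
    }
  }
  FALSE
}

# Dynamic-programming longest-common-subsequence oracle.
lcs_oracle <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  M <- matrix(0L, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      M[i + 1L, j + 1L] <- if (x[i] == y[j]) M[i, j] + 1L else
        max(M[i, j + 1L], M[i + 1L, j])
    }
  }
  M[n + 1L, m + 1L]
}

# Independent checker for the three running-span sequence constraints.
check_digit_sequence <- function(s) {
  d <- as.integer(strsplit(s, "")[[1]])
  if (any(d < 1L | d > 9L)) return("digit outside 1-9")
  if (any(table(d) > 3L)) return("digit used more than three times")
  if (length(d) > 1L && any(abs(diff(d)) == 1L))
    return("numerically consecutive neighbours")
  if (length(d) >= 6L) {
    for (i in seq_len(length(d) - 5L)) {
      w <- d[i:(i + 5L)]
      if (any(table(w) > 2L)) return("digit repeated >1 in 6-window")
    }
  }
  "ok"
}

# Random small rewriting instance for property tests.
random_instance <- function() {
  alpha <- LETTERS[1:sample(2:3, 1)]
  k <- sample(2:3, 1)
  repeat {
    lhs <- vapply(seq_len(k), function(i)
      paste(sample(alpha, sample(1:2, 1), replace = TRUE), collapse = ""),
      character(1))
    rhs <- vapply(seq_len(k), function(i)
      paste(sample(alpha, sample(1:2, 1), replace = TRUE), collapse = ""),
      character(1))
    if (!any(lhs == rhs) && !anyDuplicated(paste(lhs, rhs))) break
  }
  rs <- ruleset(data.frame(id = seq_len(k), lhs = lhs, rhs = rhs))
  start <- paste(sample(alpha, sample(2:5, 1), replace = TRUE),
                 collapse = "")
  goal <- paste(sample(alpha, sample(2:4, 1), replace = TRUE),
                collapse = "")
  list(ruleset = rs, start = start, goal = goal)
}

# ---- shared fixture: a tiny solvable task with a fully hand-checked graph
# ruleset F: 1: AB -> C, 2: CC -> A, 3: BC -> B; task ABAB -> A
fixture_ruleset <- function() {
  ruleset(data.frame(id = 1:3, lhs = c("AB", "CC", "BC"),
                     rhs = c("C", "A", "B")), id = "F")
}

fixture_graph <- function() {
  state_graph("ABAB", "A", fixture_ruleset())
}

.ev <- function(t, kind, rule = NA_integer_, pos = NA_integer_,
                state = NA_character_, x = NA_real_, y = NA_real_) {
  data.frame(t = t, kind = kind, rule = rule, pos = pos, state = state,
             x = x, y = y, stringsAsFactors = FALSE)
}

# Three hand-scripted participants on the fixture task. Every derived
# measure for these logs is computed by hand in the tests.
fixture_trials <- function() {
  task <- list(start = "ABAB", goal = "A", ruleset_id = "F")
  p1 <- rbind(
    .ev(1.0, "rule_activate", rule = 1L, x = 100, y = 500),
    .ev(1.5, "symbol_activate", pos = 0L, x = 400, y = 500),
    .ev(1.6, "state_change", rule = 1L, pos = 0L, state = "CAB"),
    .ev(4.0, "symbol_activate", pos = 1L, x = 440, y = 500),
    .ev(4.4, "rule_activate", rule = 1L, x = 240, y = 500),
    .ev(4.5, "state_change", rule = 1L, pos = 1L, state = "CC"),
    .ev(6.0, "rule_activate", rule = 2L, x = 96, y = 500),
    .ev(6.5, "symbol_activate", pos = 0L, x = 396, y = 500),
    .ev(6.6, "state_change", rule = 2L, pos = 0L, state = "A"))
  p2 <- rbind(
    .ev(2.0, "rule_activate", rule = 2L, x = 100, y = 500),
    .ev(2.5, "symbol_activate", pos = 0L, x = 400, y = 500),
    .ev(5.0, "rule_activate", rule = 1L, x = 100, y = 500),
    .ev(5.5, "symbol_activate", pos = 2L, x = 492, y = 500),
    .ev(5.6, "state_change", rule = 1L, pos = 2L, state = "ABC"),
    .ev(8.0, "symbol_activate", pos = 1L, x = 430, y = 500),
    .ev(8.5, "rule_activate", rule = 3L, x = 130, y = 500),
    .ev(8.6, "state_change", rule = 3L, pos = 1L, state = "AB"),
    .ev(10.0, "reset"),
    .ev(12.0, "rule_activate", rule = 1L, x = 100, y = 500),
    .ev(12.5, "symbol_activate", pos = 0L, x = 400, y = 500),
    .ev(12.6, "state_change", rule = 1L, pos = 0L, state = "CAB"),
    .ev(14.0, "rule_activate", rule = 1L, x = 103, y = 500),
    .ev(14.5, "symbol_activate", pos = 1L, x = 403, y = 500),
    .ev(14.6, "state_change", rule = 1L, pos = 1L, state = "CC"),
    .ev(16.0, "rule_activate", rule = 2L, x = 100, y = 500),
    .ev(16.4, "symbol_activate", pos = 0L, x = 400, y = 500),
    .ev(16.5, "state_change", rule = 2L, pos = 0L, state = "A"))
  p3 <- rbind(
    .ev(3.0, "rule_activate", rule = 1L, x = 100, y = 500),
    .ev(3.5, "symbol_activate", pos = 0L, x = 400, y = 500),
    .ev(3.6, "state_change", rule = 1L, pos = 0L, state = "CAB"),
    .ev(70.0, "symbol_activate", pos = 0L, x = 400, y = 500),
    .ev(70.5, "rule_activate", rule = 2L, x = 100, y = 500))
  list(
    trial_record("P1", 1L, "t1", task, p1, solved = TRUE, steps = 3L,
                 score = trial_score(75 - 6.6, 3), group = "A"),
    trial_record("P2", 1L, "t1", task, p2, solved = TRUE, steps = 5L,
                 score = trial_score(75 - 16.5, 5), group = "A"),
    trial_record("P3", 1L, "t1", task, p3, solved = FALSE, steps = 1L,
                 score = 0L, group = "A"))
}
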