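test_that("apply_rule substitutes matched spans and signals invalidity", {
  r <- rule(1, "AB", "C")
  expect_identical(apply_rule("XABY", r, 1), "XCY")
  expect_identical(apply_rule("XABY", r, 0), NA_character_)
  expect_identical(apply_rule("AA", rule(1, "A", "AA"), 0), "AAA")
  # rule must fit within the string
  expect_identical(apply_rule("XA", r, 1), NA_character_)
  expect_error(apply_rule("XABY", r, 4), "position")
  expect_error(apply_rule("XABY", r, -1), "position")
})

test_that("applying a rule and its reverse restores the original string", {
  set.seed(1)
  for (i in 1:50) {
    inst <- random_instance()
    rs <- inst$ruleset
    mvs <- bf_moves(inst$start, rs)
    for (mv in mvs) {
      k <- match(mv$rule, rs$ids)
      back <- apply_rule(mv$to, rule(99L, rs$rhs[k], rs$lhs[k]), mv$pos)
      expect_identical(back, inst$start)
    }
  }
})

test_that("state graphs enumerate exactly the reachable states", {
  rs <- ruleset(list(rule(1, "A", "B")))
  g <- state_graph("AA", "BB", rs)
  expect_setequal(g$nodes, c("AA", "AB", "BA", "BB"))
  expect_identical(g$dist[["AA"]], 2)
  expect_identical(g$dist[["BB"]], 0)
  expect_false(g$truncated)

  # start == goal
  g2 <- state_graph("AA", "AA", rs)
  expect_identical(g2$dist[["AA"]], 0)
  expect_true("AA" %in% g2$nodes)

  # unreachable goal: no rule matches "A"
  g3 <- state_graph("A", "B", ruleset(list(rule(1, "B", "A"))))
  expect_identical(g3$dist[["A"]], Inf)
})

test_that("every graph edge is a valid application and none is missing", {
  set.seed(2)
  for (i in 1:30) {
    inst <- random_instance()
    g <- state_graph(inst$start, inst$goal, inst$ruleset,
                     caps = graph_caps(max_depth = 4L, max_len = 8L))
    if (g$truncated) next
    for (s in setdiff(g$nodes,
                      if (g$goal_unreachable) g$goal else character(0))) {
      expected <- bf_moves(s, inst$ruleset)
      expected <- Filter(function(m) nchar(m$to) <= 8L, expected)
      got <- g$edges[g$edges$from == s, ]
      expect_equal(nrow(got), length(expected))
    }
  }
})

test_that("minimal solution counts match exhaustive sequence enumeration", {
  rs <- ruleset(list(rule(1, "A", "B")))
  g <- state_graph("AA", "BB", rs)
  expect_identical(count_minimal_solutions(g), 2L)

  # linear chain: exactly one applicable move per state
  chain <- ruleset(data.frame(id = 1:2, lhs = c("AB", "CB"),
                              rhs = c("CB", "DB")))
  gc <- state_graph("AB", "DB", chain)
  expect_identical(count_minimal_solutions(gc), 1L)

  # start == goal counts the empty sequence
  expect_identical(count_minimal_solutions(state_graph("AA", "AA", rs)), 1L)

  # all-acyclic-solutions mode is bounded below by the minimal count
  expect_gte(count_minimal_solutions(g, minimal_only = FALSE), 2L)
})

test_that("median remaining solution length follows the path distribution", {
  # unique 3-step path
  chain <- ruleset(data.frame(id = 1:3, lhs = c("AB", "CB", "DB"),
                              rhs = c("CB", "DB", "EB")))
  g <- state_graph("AB", "EB", chain)
  expect_equal(median_remaining_solution_length("AB", g), 3)

  # two acyclic paths of lengths 2 and 3 -> median 2.5
  g2 <- state_graph("S", "G", ruleset(data.frame(
    id = 1:6, lhs = c("S", "M", "S", "Q", "R", "zz"),
    rhs = c("M", "G", "Q", "R", "G", "z"))))
  lens <- all_solution_lengths("S", g2, path_cap = 10)
  expect_setequal(lens, c(2L, 3L))  # S->M->G and S->Q->R->G
  expect_identical(median_remaining_solution_length("S", g2), 2.5)

  # dead-end state
  dead <- state_graph("A", "B", ruleset(list(rule(1, "C", "B"))))
  expect_identical(median_remaining_solution_length("A", dead), Inf)
})

test_that("commutative transitions are detected exactly", {
  rs <- ruleset(list(rule(1, "A", "B")))
  expect_true(has_commutative_transition(state_graph("AA", "BB", rs)))

  chain <- ruleset(data.frame(id = 1:2, lhs = c("AB", "CB"),
                              rhs = c("CB", "DB")))
  expect_false(has_commutative_transition(state_graph("AB", "DB", chain)))

  # two-step convergence via different rule pairs is NOT commutative
  conv <- ruleset(data.frame(
    id = 1:4, lhs = c("S", "S", "M", "N"), rhs = c("M", "N", "W", "W")))
  gconv <- state_graph("S", "W", conv)
  expect_false(has_commutative_transition(gconv))
  expect_false(bf_commutative(gconv, conv))
})

test_that("commutativity agrees with brute force on random instances", {
  set.seed(3)
  n_checked <- 0L
  for (i in 1:40) {
    inst <- random_instance()
    g <- state_graph(inst$start, inst$goal, inst$ruleset,
                     caps = graph_caps(max_depth = 4L, max_len = 7L))
    if (g$truncated) next
    expect_identical(has_commutative_transition(g),
                     bf_commutative(g, inst$ruleset))
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 10L)
})

test_that("wrong-turn availability is judged against minimal paths", {
  # pure linear chain: no off-path successor anywhere
  chain <- ruleset(data.frame(id = 1:2, lhs = c("AB", "CB"),
                              rhs = c("CB", "DB")))
  expect_false(wrong_turn_everywhere(state_graph("AB", "DB", chain)))

  # every on-path state also has a dead-end successor
  withturns <- ruleset(data.frame(
    id = 1:5, lhs = c("A", "B", "C", "A", "B"),
    rhs = c("B", "C", "c", "a", "b")))
  g <- state_graph("A", "C", withturns)
  expect_true(wrong_turn_everywhere(g))

  # start == goal is vacuously TRUE
  expect_true(wrong_turn_everywhere(
    state_graph("A", "A", ruleset(list(rule(1, "A", "B"))))))

  expect_error(wrong_turn_everywhere(
    state_graph("A", "B", ruleset(list(rule(1, "B", "A"))))),
    "not reachable")
})

test_that("ruleset isomorphism is a symbol-relabelling bijection", {
  expect_true(rulesets_isomorphic(ruleset(list(rule(1, "A", "B"))),
                                  ruleset(list(rule(1, "C", "D")))))
  expect_false(rulesets_isomorphic(ruleset(list(rule(1, "A", "B"))),
                                   ruleset(list(rule(1, "C", "C")))))
  a <- ruleset(list(rule(1, "AB", "A"), rule(2, "B", "AB")))
  b <- ruleset(list(rule(1, "XY", "X"), rule(2, "Y", "YX")))
  expect_false(rulesets_isomorphic(a, b))
  # but the order-preserving relabelling IS found
  b2 <- ruleset(list(rule(1, "XY", "X"), rule(2, "Y", "XY")))
  expect_true(rulesets_isomorphic(a, b2))
  # rule order must not matter (multiset comparison)
  a2 <- ruleset(list(rule(1, "B", "AB"), rule(2, "AB", "A")))
  expect_true(rulesets_isomorphic(a, a2))
})

test_that("breadth-first distances equal exhaustive enumeration minima", {
  set.seed(4)
  n_checked <- 0L
  for (i in 1:40) {
    inst <- random_instance()
    g <- state_graph(inst$start, inst$goal, inst$ruleset,
                     caps = graph_caps(max_depth = 5L, max_len = 7L))
    if (g$truncated) next
    d_bf <- bf_distance(inst$start, inst$goal, inst$ruleset, depth_cap = 5L)
    d_g <- g$dist[[inst$start]]
    if (is.finite(d_g) || is.finite(d_bf))
      expect_identical(d_g, as.numeric(d_bf))
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 10L)
})

test_that("taskset JSON and edge TSV round trips preserve content", {
  rs <- fixture_ruleset()
  ts <- structure(list(id = "fix", ruleset = rs,
                       tasks = data.frame(start = "ABAB", goal = "A",
                                          min_solution_length = 3L,
                                          n_minimal_solutions = 2L),
                       balance = table(3L)), class = "taskset")
  f <- tempfile(fileext = ".json")
  write_taskset(ts, f)
  back <- read_taskset(f)
  expect_identical(back$ruleset$lhs, rs$lhs)
  expect_identical(back$ruleset$rhs, rs$rhs)
  expect_identical(back$tasks$start, ts$tasks$start)
  expect_identical(back$tasks$min_solution_length, 3L)

  g <- fixture_graph()
  tsv <- tempfile(fileext = ".tsv")
  write_graph_tsv(g, tsv)
  ed <- read.delim(tsv, stringsAsFactors = FALSE)
  expect_identical(nrow(ed), nrow(g$edges))
  expect_identical(sort(names(ed)),
                   sort(c("from_state", "rule_id", "position", "to_state")))
})
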