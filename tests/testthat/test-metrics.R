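test_that("attempts are extracted as rule/symbol pairs in either order", {
  tr <- fixture_trials()[[1]]
  at <- extract_attempts(tr)
  expect_identical(nrow(at), 3L)
  expect_true(all(at$valid))
  expect_identical(at$t_start, c(1.0, 4.0, 6.0))
  expect_identical(at$t_end, c(1.5, 4.4, 6.5))
  expect_identical(at$rule, c(1L, 1L, 2L))
  expect_identical(at$pos, c(0L, 1L, 0L))

  tr2 <- fixture_trials()[[2]]
  at2 <- extract_attempts(tr2)
  expect_identical(nrow(at2), 6L)
  expect_identical(at2$valid, c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE))

  # empty event list
  task <- list(start = "A", goal = "A", ruleset_id = "F")
  empty <- trial_record("PX", 1L, "t1", task, empty_events(), solved = TRUE,
                        steps = 0L)
  expect_identical(nrow(extract_attempts(empty)), 0L)
})

test_that("malformed double activations are discarded with a warning", {
  task <- list(start = "ABAB", goal = "A", ruleset_id = "F")
  ev <- rbind(
    .ev(1.0, "rule_activate", rule = 1L, x = 0, y = 0),
    .ev(2.0, "rule_activate", rule = 2L, x = 0, y = 0),
    .ev(2.5, "symbol_activate", pos = 0L, x = 0, y = 0))
  tr <- trial_record("PX", 1L, "t1", task, ev, solved = FALSE, steps = 0L)
  expect_warning(at <- extract_attempts(tr), "discarding")
  expect_identical(nrow(at), 1L)
  expect_identical(at$rule, 2L)
})

test_that("between-rule times follow the gap convention", {
  tr <- fixture_trials()[[1]]
  expect_equal(between_rule_times(tr), c(2.5, 1.6))
  expect_equal(between_rule_times(tr, mode = "end_to_end"),
               c(4.4 - 1.5, 6.5 - 4.4))
  expect_equal(between_rule_times(fixture_trials()[[2]]),
               c(2.5, 2.5, 3.5, 1.5, 1.5))
  expect_equal(between_rule_times(fixture_trials()[[3]]), 70.0 - 3.5)

  # single attempt -> empty
  task <- list(start = "ABAB", goal = "A", ruleset_id = "F")
  one <- trial_record("PX", 1L, "t1", task, rbind(
    .ev(1, "rule_activate", rule = 1L, x = 0, y = 0),
    .ev(2, "symbol_activate", pos = 0L, x = 0, y = 0)),
    solved = FALSE, steps = 0L)
  expect_length(between_rule_times(one), 0L)

  # back-to-back attempts have zero gap
  two <- trial_record("PX", 1L, "t1", task, rbind(
    .ev(1, "rule_activate", rule = 1L, x = 0, y = 0),
    .ev(2, "symbol_activate", pos = 0L, x = 0, y = 0),
    .ev(2, "rule_activate", rule = 2L, x = 0, y = 0),
    .ev(3, "symbol_activate", pos = 0L, x = 0, y = 0)),
    solved = FALSE, steps = 0L)
  expect_equal(between_rule_times(two), 0)
})

test_that("cursor speeds are straight-line distances over click gaps", {
  expect_equal(cursor_speed(fixture_trials()[[1]]),
               mean(c(600, 500, 600)))
  expect_equal(cursor_speed(fixture_trials()[[2]]),
               mean(c(600, 784, 600, 600, 600, 750)))
  # identical coordinates give zero speed
  task <- list(start = "ABAB", goal = "A", ruleset_id = "F")
  same <- trial_record("PX", 1L, "t1", task, rbind(
    .ev(1, "rule_activate", rule = 1L, x = 10, y = 10),
    .ev(2, "symbol_activate", pos = 0L, x = 10, y = 10)),
    solved = FALSE, steps = 0L)
  expect_equal(cursor_speed(same), 0)
  # zero time delta is skipped with a warning
  zero <- trial_record("PX", 1L, "t1", task, rbind(
    .ev(1, "rule_activate", rule = 1L, x = 10, y = 10),
    .ev(1, "symbol_activate", pos = 0L, x = 90, y = 10)),
    solved = FALSE, steps = 0L)
  expect_warning(v <- cursor_speed(zero), "zero time")
  expect_true(is.na(v))
})

test_that("state trajectories replay undo and reset", {
  st <- trial_states(fixture_trials()[[2]])
  expect_identical(st$state,
                   c("ABAB", "ABC", "AB", "ABAB", "CAB", "CC", "A"))
  task <- list(start = "AB", goal = "C", ruleset_id = "F")
  ev <- rbind(
    .ev(1, "state_change", rule = 1L, pos = 0L, state = "C"),
    .ev(2, "undo"),
    .ev(3, "state_change", rule = 1L, pos = 0L, state = "C"))
  tr <- trial_record("PX", 1L, "t1", task, ev, solved = TRUE, steps = 2L)
  expect_identical(trial_states(tr)$state, c("AB", "C", "AB", "C"))
})

test_that("optimality statistics match the hand-traced fixture", {
  trials <- fixture_trials()
  graphs <- task_graphs(trials, list(F = fixture_ruleset()))
  g <- graphs[["ABAB -> A"]]
  expect_identical(g$dist[["ABAB"]], 3)
  expect_identical(g$dist[["AB"]], Inf)

  om <- optimality_stats(trials, graphs, mode = "minimal_distance")
  # P1 solved in 3 = minimal: optimal at distances 3, 2, 1
  p1 <- om[om$participant == "P1", ]
  expect_equal(p1$distance, c(1, 2, 3))
  expect_equal(p1$n_optimal, c(1, 1, 1))
  # P2 wandered first: non-optimal at the first ABAB visit and at ABC
  p2 <- om[om$participant == "P2", ]
  expect_equal(p2$distance, c(1, 2, 3))
  expect_equal(p2$n, c(1, 2, 2))
  expect_equal(p2$n_optimal, c(1, 1, 1))
  # P3 never solved: absent in minimal-distance mode
  expect_false("P3" %in% om$participant)

  og <- optimality_stats(trials, graphs, mode = "median_group")
  # unsolved trials fail in every group they touch
  p3 <- og[og$participant == "P3", ]
  expect_equal(sum(p3$n_optimal), 0)
  expect_setequal(p3$distance, c(2, 3))
  # P2: fails at its first pass (6 observed attempts from ABAB median 3),
  # succeeds after the reset
  p2g <- og[og$participant == "P2", ]
  expect_equal(p2g$n[p2g$distance == 3], 2)
  expect_equal(p2g$n_optimal[p2g$distance == 3], 1)
})

test_that("strategy weights reproduce the conversion identities", {
  w <- strategy_weights(0.5, 0.5)
  expect_equal(unlist(w), c(w_t = 1/3, w_w = 1/3, w_i = 1/3))
  w2 <- strategy_weights(2/3, 1/2)
  expect_equal(unlist(w2), c(w_t = 0.5, w_w = 0.25, w_i = 0.25))
  # sum-to-one identity across the preference grid
  g <- expand.grid(x = seq(0.05, 0.95, by = 0.09),
                   y = seq(0.05, 0.95, by = 0.09))
  ww <- strategy_weights(g$x, g$y)
  expect_true(all(abs(rowSums(ww) - 1) < 1e-9))
  expect_true(all(ww >= 0 & ww <= 1))
  # weights do not depend on z
  expect_identical(strategy_weights(0.4, 0.7, 0.1),
                   strategy_weights(0.4, 0.7, 0.9))
  expect_warning(strategy_weights(0, 0.5), "clamped")
  w0 <- suppressWarnings(strategy_weights(0, 1))
  expect_equal(sum(w0), 1)
})

test_that("working-memory recall is scored right-aligned by offset", {
  tab <- wm_correct_by_offset("123456789432", "9432")
  expect_identical(tab$correct[tab$offset <= 3], rep(TRUE, 4))
  expect_identical(sum(tab$correct), 4L)
  # a wrong final digit breaks only offset 0
  tab2 <- wm_correct_by_offset("123456789432", "9431")
  expect_false(tab2$correct[tab2$offset == 0])
  expect_true(all(tab2$correct[tab2$offset %in% 1:3]))
  # empty response
  tab3 <- wm_correct_by_offset("123456789432", "")
  expect_false(any(tab3$correct))
})

test_that("wm scores follow the logistic crossing construction", {
  set.seed(20)
  # responder with sharp capacity ~5: recall almost certain below offset 5
  outcomes <- lapply(1:20, function(i) {
    len <- sample(12:21, 1)
    seqs <- make_digit_sequence(len)
    ch <- rev(strsplit(seqs, "")[[1]])
    p <- plogis(2.5 * (5 - 0:(len - 1)))
    typed <- ifelse(runif(len) < p, ch,
                    vapply(ch, function(d)
                      sample(setdiff(as.character(1:9), d), 1), ""))
    list(sequence = seqs, response = paste(rev(typed), collapse = ""))
  })
  sc <- wm_score(outcomes)
  expect_gt(as.numeric(sc), 4)
  expect_lt(as.numeric(sc), 8)

  # perfect recall of exactly the final three digits
  out3 <- lapply(1:20, function(i) {
    s <- make_digit_sequence(14)
    list(sequence = s, response = substr(s, 12, 14))
  })
  sc3 <- wm_score(out3)
  expect_gte(as.numeric(sc3), 3)
  expect_lte(as.numeric(sc3), 4.5)

  # all wrong -> floor score of 1
  bad <- list(list(sequence = "121212121212", response = ""))
  expect_identical(as.numeric(wm_score(bad)), 1)
  expect_identical(attr(wm_score(bad), "flag"), "all_wrong")

  # all correct -> ceiling score, flagged
  good <- lapply(1:3, function(i) {
    s <- make_digit_sequence(12)
    list(sequence = s, response = s)
  })
  expect_identical(as.numeric(wm_score(good)), 12)
})

test_that("exclusion criteria remove non-engaged participants", {
  set.seed(21)
  task <- list(start = "ABAB", goal = "A", ruleset_id = "F")
  mk_trial <- function(p, s, solved) {
    trial_record(p, s, "t1", task, empty_events(), solved = solved,
                 steps = 0L)
  }
  wm_good <- function(p) lapply(1:4, function(s) {
    seqs <- replicate(6, make_digit_sequence(12))
    lapply(seqs, function(q)
      list(participant = p, session = s, sequence = q,
           response = substr(q, 9, 12)))
  })
  wm <- c(unlist(wm_good("good"), recursive = FALSE),
          unlist(wm_good("nosolve"), recursive = FALSE),
          # inattentive responder: always types a shifted digit, so the
          # final digit is never recalled
          unlist(lapply(1:4, function(s) {
            seqs <- replicate(6, make_digit_sequence(12))
            lapply(seqs, function(q) {
              d <- as.integer(strsplit(q, "")[[1]])
              list(participant = "guess", session = s, sequence = q,
                   response = paste((d %% 9L) + 1L, collapse = ""))
            })
          }), recursive = FALSE))
  trials <- c(
    lapply(1:4, function(s) mk_trial("good", s, TRUE)),
    lapply(1:4, function(s) mk_trial("guess", s, TRUE)),
    lapply(1:4, function(s) mk_trial("nosolve", s, s != 3)),
    list(mk_trial("incomplete", 1L, TRUE)))
  res <- apply_exclusions(trials, wm)
  expect_true("good" %in% res$included)
  expect_false("nosolve" %in% res$included)
  expect_false("incomplete" %in% res$included)
  expect_false("guess" %in% res$included)
  rep <- res$report
  expect_identical(rep$reason[rep$participant == "guess"],
                   "final-digit recall at or below chance")
  expect_identical(rep$reason[rep$participant == "nosolve"],
                   "no solve in every session")
  expect_identical(rep$reason[rep$participant == "incomplete"],
                   "incomplete")
})

test_that("event logs survive a JSON-Lines round trip", {
  trials <- fixture_trials()
  f <- tempfile(fileext = ".jsonl")
  write_event_log(trials, f)
  back <- read_event_log(f)
  expect_length(back, 3L)
  for (i in 1:3) {
    expect_identical(back[[i]]$participant, trials[[i]]$participant)
    expect_identical(back[[i]]$solved, trials[[i]]$solved)
    expect_equal(back[[i]]$events$t, trials[[i]]$events$t)
    expect_identical(back[[i]]$events$kind, trials[[i]]$events$kind)
  }
  expect_equal(between_rule_times(back[[1]]), c(2.5, 1.6))
})

test_that("block measures aggregate the fixture exactly", {
  bm <- block_measures(fixture_trials())
  expect_identical(nrow(bm), 3L)
  expect_equal(bm$prop_solved, c(1, 1, 0))
  expect_equal(bm$mean_brt[bm$participant == "P1"], mean(c(2.5, 1.6)))
  expect_equal(bm$mean_brt[bm$participant == "P2"],
               mean(c(2.5, 2.5, 3.5, 1.5, 1.5)))
  expect_equal(bm$mean_score[bm$participant == "P1"], 228)
  expect_equal(bm$mean_score[bm$participant == "P2"], 117)
})
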