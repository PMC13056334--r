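# Shared small study materials for simulator tests, built once per run.
local_materials <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_study_tasksets(n_per_length = 8L, seed = 42)
    cache
  }
})

test_that("digit sequences respect all three printed constraints", {
  set.seed(30)
  for (i in 1:200) {
    s <- make_digit_sequence(sample(12:21, 1))
    expect_identical(check_digit_sequence(s), "ok")
  }
  expect_error(make_digit_sequence(11), "length")
  expect_error(make_digit_sequence(22), "length")
  # seeded determinism
  expect_identical(make_digit_sequence(15, seed = 3),
                   make_digit_sequence(15, seed = 3))
})

test_that("an oracle-valued agent solves short tasks near-optimally", {
  mats <- local_materials()
  ts <- mats$a
  tasks4 <- ts$tasks[ts$tasks$min_solution_length == 4L, ]
  oracle <- agent_profile(mechanism = "heuristic_search",
                          value_source = "oracle",
                          softmax_temperature = 1e-3, slip_prob = 0)
  set.seed(31)
  res <- lapply(seq_len(nrow(tasks4)), function(i) {
    tk <- tasks4[i, ]
    g <- state_graph(tk$start, tk$goal, ts$ruleset)
    simulate_trial(oracle, list(start = tk$start, goal = tk$goal,
                                ruleset_id = "A"), g, agent_memory())
  })
  solved <- vapply(res, function(r) r$solved, logical(1))
  steps <- vapply(res, function(r) r$steps, integer(1))
  expect_gte(mean(solved), 0.9)
  # greedy on exact values walks a minimal path
  expect_true(all(steps[solved] == 4L))
})

test_that("a naive agent's solution rate sits in the baseline regime", {
  mats <- local_materials()
  naive <- agent_profile(mechanism = "heuristic_search",
                         softmax_temperature = 5)
  set.seed(32)
  solved <- unlist(lapply(list(mats$a, mats$b), function(ts) {
    vapply(seq_len(nrow(ts$tasks)), function(i) {
      tk <- ts$tasks[i, ]
      g <- state_graph(tk$start, tk$goal, ts$ruleset)
      simulate_trial(naive, list(start = tk$start, goal = tk$goal,
                                 ruleset_id = ts$ruleset$id), g,
                     agent_memory())$solved
    }, logical(1))
  }))
  expect_gte(mean(solved), 0.04)
  expect_lte(mean(solved), 0.30)
})

test_that("simulated trials produce parseable, consistent event logs", {
  mats <- local_materials()
  design <- study_design()
  profs <- replicate(4, agent_profile(softmax_temperature = 0.3),
                     simplify = FALSE)
  coh <- simulate_cohort(design, profs, list(a = mats$a, b = mats$b),
                         transfer_enabled = FALSE, seed = 7)
  expect_length(coh$trials, 4L * 8L * 12L)
  # logs parse with no warnings and replay to the recorded outcome
  expect_silent({
    for (tr in coh$trials[seq(1, 384, by = 19)]) {
      at <- extract_attempts(tr)
      st <- trial_states(tr)
      expect_identical(tr$solved,
                       st$state[nrow(st)] == tr$task$goal)
      expect_identical(tr$steps,
                       sum(tr$events$kind == "state_change"))
      expect_true(all(diff(tr$events$t) >= 0))
      expect_lte(max(c(0, tr$events$t)), 75)
      if (tr$solved && tr$steps >= 1)
        expect_identical(tr$score,
                         trial_score(max(75 - max(tr$events$t), 0),
                                     tr$steps))
    }
  })
  # every state change is a valid rule application from the current state
  rs_list <- list(A = mats$a$ruleset, B = mats$b$ruleset)
  for (tr in coh$trials[c(1, 50, 200)]) {
    rs <- rs_list[[tr$task$ruleset_id]]
    stack <- tr$task$start
    for (k in seq_len(nrow(tr$events))) {
      kind <- tr$events$kind[k]
      if (kind == "reset") stack <- stack[1L]
      if (kind == "undo" && length(stack) > 1L) stack <- stack[-length(stack)]
      if (kind == "state_change") {
        i <- match(tr$events$rule[k], rs$ids)
        nxt <- apply_rule(stack[length(stack)],
                          rule(rs$ids[i], rs$lhs[i], rs$rhs[i]),
                          tr$events$pos[k])
        expect_identical(nxt, tr$events$state[k])
        stack <- c(stack, nxt)
      }
    }
  }
})

test_that("cohort simulation is deterministic under a fixed seed", {
  mats <- local_materials()
  design <- study_design()
  profs <- replicate(2, agent_profile(softmax_temperature = 0.3),
                     simplify = FALSE)
  c1 <- simulate_cohort(design, profs, list(a = mats$a, b = mats$b),
                        transfer_enabled = TRUE, seed = 9)
  c2 <- simulate_cohort(design, profs, list(a = mats$a, b = mats$b),
                        transfer_enabled = TRUE, seed = 9)
  d1 <- tempfile(); d2 <- tempfile()
  write_cohort(c1, d1); write_cohort(c2, d2)
  for (f in c("trials.jsonl", "strategy.csv", "wm.csv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("the block schedule matches the session structure", {
  mats <- local_materials()
  design <- study_design()
  profs <- list(agent_profile(softmax_temperature = 0.3))
  coh <- simulate_cohort(design, profs, list(a = mats$a, b = mats$b),
                         transfer_enabled = FALSE, seed = 10,
                         groups = "A")
  bm <- block_measures(coh$trials)
  expect_setequal(bm$block, c("p1", "t1", "t2", "t3", "t4", "t5", "t6",
                              "p2"))
  expect_identical(bm$session[match(c("p1", "t1", "t2", "t6", "p2"),
                                    bm$block)],
                   c(1L, 1L, 2L, 4L, 4L))
  # probe tasks come from the other taskset and never repeat across probes
  probe_tasks <- vapply(
    Filter(function(tr) tr$block %in% c("p1", "p2"), coh$trials),
    function(tr) paste(tr$task$start, tr$task$goal), character(1))
  expect_false(anyDuplicated(probe_tasks) > 0)
  probe_rs <- vapply(
    Filter(function(tr) tr$block %in% c("p1", "p2"), coh$trials),
    function(tr) tr$task$ruleset_id, character(1))
  expect_true(all(probe_rs == "B"))
  # training trials draw from the trained taskset, distinct within block
  train_trs <- Filter(function(tr) grepl("^t", tr$block), coh$trials)
  train_tasks <- vapply(train_trs, function(tr)
    paste(tr$task$start, tr$task$goal), character(1))
  train_blocks <- vapply(train_trs, `[[`, "", "block")
  for (b in unique(train_blocks))
    expect_false(anyDuplicated(train_tasks[train_blocks == b]) > 0)
  expect_true(all(vapply(train_trs, function(tr) tr$task$ruleset_id,
                         character(1)) == "A"))
  # 20 wm trials per session, each length twice per session
  wm_sess <- vapply(coh$wm, function(w) w$session, integer(1))
  expect_identical(as.integer(table(wm_sess)), rep(20L, 4L))
  lens <- nchar(vapply(coh$wm, function(w) w$sequence, character(1)))
  expect_true(all(table(lens, wm_sess) == 2L))
})

test_that("simulated recall declines with offset and beats chance at 0", {
  set.seed(33)
  ag <- agent_profile(wm_capacity = 5)
  tabs <- do.call(rbind, lapply(1:60, function(i) {
    o <- rewritask:::.simulate_wm_trial(ag, sample(12:21, 1))
    wm_correct_by_offset(o$sequence, o$response)
  }))
  acc <- aggregate(correct ~ offset, tabs, mean)
  expect_gt(acc$correct[acc$offset == 0], 1 / 9)
  lo <- mean(acc$correct[acc$offset <= 3])
  hi <- mean(acc$correct[acc$offset >= 9])
  expect_gt(lo, hi)
  fit <- glm(correct ~ offset, binomial(), data = tabs)
  expect_lt(coef(fit)[["offset"]], 0)
})

test_that("associative learning curves rise on the trained taskset", {
  mats <- local_materials()
  design <- study_design()
  profs <- replicate(12, agent_profile(mechanism = "associative",
                                       softmax_temperature = 0.25,
                                       learning_rate = 2),
                     simplify = FALSE)
  coh <- simulate_cohort(design, profs, list(a = mats$a, b = mats$b),
                         transfer_enabled = FALSE, seed = 14)
  tr_blocks <- Filter(function(tr) grepl("^t", tr$block), coh$trials)
  block_num <- as.integer(sub("t", "",
                              vapply(tr_blocks, `[[`, "", "block")))
  solved <- vapply(tr_blocks, function(tr) tr$solved, logical(1))
  fit <- glm(solved ~ block_num, binomial())
  expect_gt(coef(fit)[["block_num"]], 0)
})
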