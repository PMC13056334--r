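#' Study design constants
#'
#' Four sessions of two 12-trial problem-solving blocks each, followed by a
#' 20-trial running-span block per session. The block schedule assigns the
#' pre-training probe (`p1`) to the first block of session 1, training
#' blocks `t1` .. `t6` to the remaining session-1 block through the first
#' block of session 4, and the post-training probe (`p2`) to the final
#' block, using probe tasks not seen in `p1`.
#'
#' @param n_sessions,blocks_per_session,trials_per_block,wm_trials_per_session
#'   Design sizes; defaults follow the standard four-session layout.
#' @return A list of class `study_design`.
#' @export
study_design <- function(n_sessions = 4L, blocks_per_session = 2L,
                         trials_per_block = 12L,
                         wm_trials_per_session = 20L) {
  structure(list(n_sessions = as.integer(n_sessions),
                 blocks_per_session = as.integer(blocks_per_session),
                 trials_per_block = as.integer(trials_per_block),
                 wm_trials_per_session = as.integer(wm_trials_per_session),
                 block_labels = c("p1", "t1", "t2", "t3", "t4", "t5", "t6",
                                  "p2"),
                 block_sessions = c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L)),
            class = "study_design")
}

#' Synthetic agent profile
#'
#' Parameterises a simulated participant. Two mechanism classes are
#' provided: `"associative"` agents learn strengths of (pattern, action)
#' associations specific to the ruleset in use, and `"heuristic_search"`
#' agents score candidate successor states with the logistic state-value
#' heuristic and learn its coefficients from the reachability outcomes of
#' states they visit. `"mixture"` agents pick a mechanism per decision.
#'
#' @param mechanism `"associative"`, `"heuristic_search"`, or `"mixture"`.
#' @param learning_rate Positive step size for associative strength updates.
#' @param softmax_temperature Positive decision temperature.
#' @param value_betas 14 reals (intercept + 13 feature coefficients) for
#'   the heuristic mechanism; defaults to zeros (naive agent).
#' @param value_source `"betas"` to score with `value_betas`, `"oracle"`
#'   to score with the true negative distance to goal (used for
#'   upper-bound checks).
#' @param mixture_weight Probability of using the heuristic mechanism when
#'   `mechanism = "mixture"`.
#' @param dt_meanlog,dt_sdlog Log-normal decision-time parameters
#'   (seconds).
#' @param dt_decay Linear decline of `dt_meanlog` per cumulative attempt
#'   (practice speed-up); floored at `dt_meanlog_min`.
#' @param dt_meanlog_min Lower floor for the decision-time location.
#' @param slip_prob Probability of attempting an invalid (rule, position)
#'   pair.
#' @param cursor_speed Mean cursor travel speed in pixels/second.
#' @param wm_capacity Logistic recall midpoint (offsets below this are
#'   mostly recalled).
#' @param wm_slope Steepness of the recall-by-offset curve.
#' @param strategy_bias Length-3 positive vector biasing the reported
#'   strategy weights (try-and-see, work-it-out, intuition).
#' @return A list of class `agent_profile`.
#' @export
agent_profile <- function(mechanism = c("heuristic_search", "associative",
                                        "mixture"),
                          learning_rate = 1, softmax_temperature = 0.5,
                          value_betas = rep(0, 14),
                          value_source = c("betas", "oracle"),
                          mixture_weight = 0.5,
                          dt_meanlog = log(1.8), dt_sdlog = 0.45,
                          dt_decay = 0.0003, dt_meanlog_min = log(0.8),
                          slip_prob = 0.06, cursor_speed = 600,
                          wm_capacity = 5, wm_slope = 1.2,
                          strategy_bias = c(1, 1, 1)) {
  mechanism <- match.arg(mechanism)
  value_source <- match.arg(value_source)
  stopifnot(softmax_temperature > 0, learning_rate > 0, dt_decay >= 0,
            length(value_betas) == 14L, length(strategy_bias) == 3L)
  structure(list(mechanism = mechanism, learning_rate = learning_rate,
                 softmax_temperature = softmax_temperature,
                 value_betas = value_betas, value_source = value_source,
                 mixture_weight = mixture_weight,
                 dt_meanlog = dt_meanlog, dt_sdlog = dt_sdlog,
                 dt_decay = dt_decay, dt_meanlog_min = dt_meanlog_min,
                 slip_prob = slip_prob, cursor_speed = cursor_speed,
                 wm_capacity = wm_capacity, wm_slope = wm_slope,
                 strategy_bias = strategy_bias),
            class = "agent_profile")
}

#' Generate a running-span digit sequence
#'
#' Digits "1" to "9", subject to the three sequence constraints: no digit
#' appears more than three times, no digit appears more than twice in any
#' window of six consecutive digits, and no adjacent pair is numerically
#' consecutive in either direction.
#'
#' @param length Sequence length in `[12, 21]`.
#' @param seed Integer seed (optional).
#' @param max_attempts Rejection-sampling budget.
#' @return A digit string.
#' @export
make_digit_sequence <- function(length, seed = NULL, max_attempts = 2000L) {
  if (length < 12L || length > 21L) stopf("length must lie in [12, 21]")
  with_seed(seed, {
    for (a in seq_len(max_attempts)) {
      digits <- integer(0)
      ok <- TRUE
      for (i in seq_len(length)) {
        cand <- sample(1:9)
        placed <- FALSE
        for (d in cand) {
          if (sum(digits == d) >= 3L) next
          if (i > 1L && abs(d - digits[i - 1L]) == 1L) next
          window <- digits[max(1L, i - 5L):(i - 1L)]
          if (i > 1L && sum(window == d) >= 2L) next
          digits <- c(digits, d)
          placed <- TRUE
          break
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) return(paste(digits, collapse = ""))
    }
    stopf("digit-sequence sampling exhausted after %d attempts",
          max_attempts)
  })
}

.softmax_sample <- function(u, temperature) {
  u <- u / temperature
  u <- u - max(u)
  p <- exp(u)
  p <- p / sum(p)
  sample.int(length(u), 1L, prob = p)
}

# Screen layout used to synthesise click coordinates.
.rule_xy <- function(rule) c(120 + 90 * rule, 620 + rnorm(1, 0, 4))
.symbol_xy <- function(pos) c(260 + 46 * pos, 300 + rnorm(1, 0, 4))

#' Simulate one problem-solving trial
#'
#' The agent repeatedly selects a (rule, position) action: the associative
#' mechanism samples from learned association strengths, the heuristic
#' mechanism scores each candidate successor with the state-value heuristic
#' (or the true distance oracle) and samples via softmax. Decision times
#' are log-normal with a location that declines with cumulative practice.
#' The trial is truncated at 75 seconds. Events carry synthesised click
#' coordinates so cursor-speed measures can be computed from the log.
#'
#' @param agent An [agent_profile()].
#' @param task List with `start`, `goal`, `ruleset_id`.
#' @param graph The task's [state_graph()].
#' @param memory Environment holding the agent's learned state (created by
#'   [agent_memory()]); updated in place.
#' @param participant,session,block,group Metadata stored on the record.
#' @param time_limit Trial time limit in seconds.
#' @return A [trial_record()].
#' @export
simulate_trial <- function(agent, task, graph, memory = agent_memory(),
                           participant = "sim", session = 1L, block = "t1",
                           group = NA_character_, time_limit = 75) {
  adj <- graph$adj %||% .adjacency(graph)
  node_id <- seq_along(graph$nodes)
  names(node_id) <- graph$nodes
  ed <- graph$edges
  rs_key <- task$ruleset_id
  s <- task$start
  t <- 0
  steps <- 0L
  ev_t <- numeric(0); ev_kind <- character(0); ev_rule <- integer(0)
  ev_pos <- integer(0); ev_state <- character(0)
  ev_x <- numeric(0); ev_y <- numeric(0)
  emit <- function(t, kind, rule = NA_integer_, pos = NA_integer_,
                   state = NA_character_, x = NA_real_, y = NA_real_) {
    ev_t[length(ev_t) + 1L] <<- t
    ev_kind[length(ev_kind) + 1L] <<- kind
    ev_rule[length(ev_rule) + 1L] <<- rule
    ev_pos[length(ev_pos) + 1L] <<- pos
    ev_state[length(ev_state) + 1L] <<- state
    ev_x[length(ev_x) + 1L] <<- x
    ev_y[length(ev_y) + 1L] <<- y
  }
  visited <- s
  prev_state <- NA_character_
  solved <- FALSE
  repeat {
    if (s == task$goal) { solved <- TRUE; break }
    out <- adj[[node_id[[s]]]]
    if (is.null(out) || !length(out)) {
      # dead end: click reset and start over (as participants do)
      if (s == task$start) break             # task unsolvable in place
      t_reset <- t + rlnorm(1, agent$dt_meanlog, agent$dt_sdlog)
      if (t_reset >= time_limit) { t <- time_limit; break }
      t <- t_reset + 0.05
      emit(t_reset, "reset")
      prev_state <- NA_character_
      s <- task$start
      visited <- c(visited, s)
      next
    }
    cand <- data.frame(rule = ed$rule[out], pos = ed$pos[out],
                       to = ed$to[out], stringsAsFactors = FALSE)
    slip <- runif(1) < agent$slip_prob
    if (slip) {
      # attempt a random invalid (rule, position) pair
      pos_all <- 0:(nchar(s) - 1L)
      bad <- expand.grid(rule = graph$ruleset$ids, pos = pos_all)
      key <- paste(bad$rule, bad$pos)
      bad <- bad[!(key %in% paste(cand$rule, cand$pos)), , drop = FALSE]
      if (nrow(bad)) {
        pick <- bad[sample.int(nrow(bad), 1L), ]
        act <- list(rule = pick$rule, pos = pick$pos, to = NA_character_)
      } else slip <- FALSE
    }
    if (!slip) {
      mech <- agent$mechanism
      if (mech == "mixture")
        mech <- if (runif(1) < agent$mixture_weight) "heuristic_search"
          else "associative"
      u <- if (mech == "heuristic_search") {
        if (agent$value_source == "oracle") {
          d <- graph$dist[cand$to]
          ifelse(is.finite(d), -d, -1e6)
        } else {
          b <- .memory_betas(memory, rs_key, agent)
          X <- feature_matrix(cand$to, rep(task$goal, nrow(cand)))
          drop(cbind(1, X) %*% b)
        }
      } else {
        .assoc_strengths(memory, rs_key, s, task$goal, cand, graph$ruleset)
      }
      # discourage immediately undoing the previous transformation
      if (!is.na(prev_state)) u <- u - 2 * (cand$to == prev_state)
      j <- .softmax_sample(u, agent$softmax_temperature)
      act <- as.list(cand[j, ])
    }
    n_att <- memory$attempts
    mu <- max(agent$dt_meanlog - agent$dt_decay * n_att,
              agent$dt_meanlog_min)
    think <- rlnorm(1, mu, agent$dt_sdlog)
    rule_first <- runif(1) < 0.5
    xy_r <- .rule_xy(act$rule)
    xy_s <- .symbol_xy(act$pos)
    travel_px <- sqrt(sum((xy_r - xy_s)^2))
    travel <- travel_px / (agent$cursor_speed * exp(rnorm(1, 0, 0.15)))
    t1 <- t + think
    t2 <- t1 + travel
    if (t2 >= time_limit) { t <- time_limit; break }
    if (rule_first) {
      emit(t1, "rule_activate", rule = act$rule, x = xy_r[1], y = xy_r[2])
      emit(t2, "symbol_activate", pos = act$pos, x = xy_s[1], y = xy_s[2])
    } else {
      emit(t1, "symbol_activate", pos = act$pos, x = xy_s[1], y = xy_s[2])
      emit(t2, "rule_activate", rule = act$rule, x = xy_r[1], y = xy_r[2])
    }
    memory$attempts <- memory$attempts + 1L
    t <- t2 + 0.05
    emit(t2 + 0.02, "rule_deactivate")
    emit(t2 + 0.02, "symbol_deactivate")
    if (!is.na(act$to)) {
      emit(t, "state_change", rule = act$rule, pos = act$pos,
           state = act$to)
      steps <- steps + 1L
      prev_state <- s
      s <- act$to
      visited <- c(visited, s)
    }
  }
  events <- data.frame(t = ev_t, kind = ev_kind, rule = ev_rule,
                       pos = ev_pos, state = ev_state, x = ev_x, y = ev_y,
                       stringsAsFactors = FALSE)
  score <- if (solved && steps >= 1L)
    trial_score(max(time_limit - t, 0), steps) else 0L
  .learn_from_trial(memory, agent, rs_key, task, graph, visited, solved)
  trial_record(participant, session, block, task, events, solved,
               steps = steps, score = score, group = group)
}

#' Create an empty agent memory
#'
#' Holds association strengths, accumulated reachability-labelled states,
#' current heuristic coefficients per ruleset (or shared when transfer is
#' enabled), and the cumulative attempt counter driving practice effects.
#'
#' @param transfer_enabled Share the heuristic coefficients and training
#'   samples across rulesets (the transfer regime) or keep them separate.
#' @return An environment.
#' @export
agent_memory <- function(transfer_enabled = FALSE) {
  m <- new.env(parent = emptyenv())
  m$assoc <- new.env(parent = emptyenv())
  m$base <- list()
  m$samples <- list()
  m$betas <- list()
  m$attempts <- 0L
  m$transfer <- isTRUE(transfer_enabled)
  m
}

.beta_key <- function(memory, rs_key) if (memory$transfer) "shared" else
  rs_key

.memory_betas <- function(memory, rs_key, agent) {
  memory$betas[[.beta_key(memory, rs_key)]] %||% agent$value_betas
}

# Pattern keys for pattern-action associations. Associations are specific
# to a rule id, so they cannot transfer to a different ruleset, but the
# patterns abstract over tasks of the same ruleset:
#  * a local-chunk key: the rule plus the symbols flanking the matched
#    span ("^"/"$" at string edges);
#  * a goal-relational key: the rule plus whether its lhs/rhs occur as
#    substrings of the goal (recognising e.g. "this rule's product appears
#    in the goal").
.chunk_key <- function(rs_key, state, rule_id, pos, lhs_len) {
  n <- nchar(state)
  left <- if (pos > 0) substr(state, pos, pos) else "^"
  rp <- pos + lhs_len + 1L
  right <- if (rp <= n) substr(state, rp, rp) else "$"
  paste0("C:", rs_key, ":", rule_id, ":", left, right)
}

.goal_key <- function(rs_key, goal, rule_id, lhs, rhs, to) {
  paste0("G:", rs_key, ":", rule_id, ":",
         as.integer(grepl(lhs, goal, fixed = TRUE)),
         as.integer(grepl(rhs, goal, fixed = TRUE)),
         as.integer(.conserves_goal_symbols(to, goal)))
}

# Pattern bit: after the move, does the state still contain at least as
# many of each symbol as the goal requires? (Recognisable at a glance;
# whether it matters for a given rule is what gets learned.)
.conserves_goal_symbols <- function(to, goal) {
  gs <- strsplit(goal, "")[[1]]
  ts <- strsplit(to, "")[[1]]
  for (sym in unique(gs))
    if (sum(ts == sym) < sum(gs == sym)) return(FALSE)
  TRUE
}

.action_keys <- function(rs_key, state, goal, rule_id, pos, to, ruleset) {
  ri <- match(rule_id, ruleset$ids)
  list(
    rk = paste0("R:", rs_key, ":", rule_id),
    ck = .chunk_key(rs_key, state, rule_id, pos, nchar(ruleset$lhs[ri])),
    gk = .goal_key(rs_key, goal, rule_id, ruleset$lhs[ri],
                   ruleset$rhs[ri], to),
    xk = paste0("X:", rs_key, ":", state, "|", goal, "|", rule_id, "@",
                pos))
}

.assoc_strengths <- function(memory, rs_key, state, goal, cand, ruleset) {
  vapply(seq_len(nrow(cand)), function(i) {
    k <- .action_keys(rs_key, state, goal, cand$rule[i], cand$pos[i],
                      cand$to[i], ruleset)
    0.3 * (memory$assoc[[k$rk]] %||% 0) +
      0.7 * (memory$assoc[[k$ck]] %||% 0) +
      2.0 * (memory$assoc[[k$gk]] %||% 0) +
      3.0 * (memory$assoc[[k$xk]] %||% 0)
  }, numeric(1))
}

# Advantage-style delta update: a pattern's strength drifts by the
# difference between the observed segment outcome and a running success
# baseline, so patterns used on above-average-successful segments drift
# positive and below-average ones drift negative, while unexplored
# patterns stay at the (average) zero point.
.rw_update <- function(memory, key, y, rate, baseline) {
  s <- memory$assoc[[key]] %||% 0
  memory$assoc[[key]] <- s + rate * (y - baseline)
}

.learn_from_trial <- function(memory, agent, rs_key, task, graph, visited,
                              solved) {
  if (agent$mechanism %in% c("associative", "mixture")) {
    # segment the visited trajectory at resets: moves on a segment that
    # ended in a dead end were a failure (y = 0); moves on the final
    # segment of a solved trial were a success (y = 1)
    starts <- which(visited == task$start)
    ends <- c(starts[-1L] - 1L, length(visited))
    rate <- 0.25 * agent$learning_rate
    base <- memory$base[[rs_key]] %||% 0.2
    for (j in seq_along(starts)) {
      seg <- visited[starts[j]:ends[j]]
      y <- as.integer(solved && ends[j] == length(visited))
      memory$base[[rs_key]] <- base + 0.05 * (y - base)
      base <- memory$base[[rs_key]]
      ed <- graph$edges
      for (i in seq_len(length(seg) - 1L)) {
        sel <- which(ed$from == seg[i] & ed$to == seg[i + 1L])
        if (!length(sel)) next
        e <- sel[1L]
        k <- .action_keys(rs_key, seg[i], task$goal, ed$rule[e], ed$pos[e],
                          ed$to[e], graph$ruleset)
        .rw_update(memory, k$rk, y, rate, base)
        .rw_update(memory, k$ck, y, rate, base)
        .rw_update(memory, k$gk, y, rate, base)
        if (y == 1L) .rw_update(memory, k$xk, y, 4 * rate, base)
      }
    }
  }
  if (agent$mechanism %in% c("heuristic_search", "mixture") &&
      agent$value_source == "betas") {
    key <- .beta_key(memory, rs_key)
    st <- unique(visited)
    lab <- as.integer(is.finite(graph$dist[st]))
    memory$samples[[key]] <- rbind(
      memory$samples[[key]],
      data.frame(state = st, goal = task$goal, value = lab,
                 stringsAsFactors = FALSE))
  }
  invisible(memory)
}

#' Refit an agent's heuristic coefficients from accumulated samples
#'
#' Ridge-regularised logistic refit of the 14 coefficients on the
#' reachability-labelled states the agent has visited. Called between
#' blocks by [simulate_cohort()].
#'
#' @param memory An [agent_memory()].
#' @param rs_key Ruleset id whose coefficient set to refit (the shared set
#'   when the memory was created with transfer enabled).
#' @param max_samples Most recent samples retained for the fit.
#' @param shrink_n0 Shrinkage constant: fitted coefficients are scaled by
#'   `n / (n + shrink_n0)`, so early fits stay close to the naive prior
#'   and the heuristic consolidates gradually with evidence.
#' @return The updated coefficient vector, invisibly.
#' @export
refit_agent_heuristic <- function(memory, rs_key, max_samples = 4000L,
                                  shrink_n0 = 600) {
  key <- .beta_key(memory, rs_key)
  smp <- memory$samples[[key]]
  if (is.null(smp) || nrow(smp) < 20L || length(unique(smp$value)) < 2L)
    return(invisible(NULL))
  if (nrow(smp) > max_samples)
    smp <- smp[seq.int(nrow(smp) - max_samples + 1L, nrow(smp)), ]
  # balance classes so the skewed on-policy state distribution does not
  # dominate the intercept
  n1 <- sum(smp$value == 1L); n0 <- sum(smp$value == 0L)
  if (n1 > 0L && n0 > 0L) {
    k <- min(n1, n0)
    keep <- c(sample(which(smp$value == 1L), k),
              sample(which(smp$value == 0L), k))
    smp <- smp[sort(keep), ]
  }
  X <- feature_matrix(smp$state, smp$goal)
  beta <- .ridge_logistic(cbind(1, X), smp$value, lambda = 1e-3)
  # evidence-proportional shrinkage toward the naive (zero) prior: skill
  # consolidates gradually rather than after a single block
  beta <- beta * nrow(smp) / (nrow(smp) + shrink_n0)
  memory$betas[[key]] <- beta
  invisible(beta)
}

.simulate_wm_trial <- function(agent, len) {
  sequence <- make_digit_sequence(len)
  seq_ch <- rev(strsplit(sequence, "")[[1]])
  p <- expit(agent$wm_slope * (agent$wm_capacity - (seq_len(len) - 1L)))
  recall <- runif(len) < p
  n_typed <- min(len, max(1L, round(agent$wm_capacity + rnorm(1, 1, 1))))
  typed <- character(n_typed)
  for (k in seq_len(n_typed)) {
    typed[k] <- if (recall[k]) seq_ch[k] else
      sample(setdiff(as.character(1:9), seq_ch[k]), 1L)
  }
  list(sequence = sequence, response = paste(rev(typed), collapse = ""))
}

.strategy_report <- function(agent) {
  w <- as.numeric(agent$strategy_bias) + 0.15 * rgamma(3, 2, 2)
  w <- pmin(pmax(w / sum(w), 0.02), 0.96)
  w <- w / sum(w)
  x <- w[1] / (w[1] + w[2])
  y <- w[2] / (w[2] + w[3])
  z <- w[3] / (w[3] + w[1])
  c(x = x, y = y, z = z)
}

#' Simulate a complete synthetic study dataset
#'
#' Runs every agent through the full block schedule on a pair of tasksets,
#' producing event logs, per-block strategy reports, and running-span
#' working-memory trials in the formats the behavioural-measure functions
#' consume. Agents in group A train on taskset `a` and are probed on
#' taskset `b`; group B is reversed. When `transfer_enabled` is TRUE,
#' heuristic agents carry their learned state-value coefficients across
#' tasksets (so the post-training probe benefits from training); when
#' FALSE, each ruleset gets its own coefficients and probe blocks start
#' naive.
#'
#' @param design A [study_design()].
#' @param profiles List of [agent_profile()] objects, one per participant.
#' @param tasksets List with elements `a` and `b` from
#'   [generate_taskset()].
#' @param transfer_enabled Logical flag selecting the transfer regime.
#' @param seed Integer seed.
#' @param groups Optional character vector assigning each profile to group
#'   `"A"` or `"B"`; defaults to alternating.
#' @param graphs Optional precomputed graphs (from a previous run) keyed as
#'   in [task_graphs()].
#' @return List with `trials` (list of [trial_record()]), `wm` (list of
#'   outcome records), `strategy` (data.frame of per-block reports),
#'   `graphs`, `design`, `transfer_enabled`.
#' @export
simulate_cohort <- function(design, profiles, tasksets,
                            transfer_enabled = FALSE, seed = NULL,
                            groups = NULL, graphs = NULL) {
  with_seed(seed, {
    n <- length(profiles)
    groups <- groups %||% rep_len(c("A", "B"), n)
    if (is.null(graphs)) {
      graphs <- list()
      for (ts in tasksets) {
        for (i in seq_len(nrow(ts$tasks))) {
          tk <- ts$tasks[i, ]
          key <- .graph_key(tk$start, tk$goal)
          g <- state_graph(tk$start, tk$goal, ts$ruleset,
                           caps = graph_caps(max_depth = 40L,
                                             max_nodes = 4000L))
          g$adj <- .adjacency(g)
          graphs[[key]] <- g
        }
      }
    }
    trials <- list()
    wm <- list()
    strat <- list()
    for (pi in seq_len(n)) {
      agent <- profiles[[pi]]
      pid <- sprintf("P%02d", pi)
      grp <- groups[pi]
      train_ts <- if (grp == "A") tasksets$a else tasksets$b
      probe_ts <- if (grp == "A") tasksets$b else tasksets$a
      memory <- agent_memory(transfer_enabled)
      train_order <- sample(nrow(train_ts$tasks))
      if (nrow(probe_ts$tasks) < 2L * design$trials_per_block)
        stopf("probe taskset too small: %d tasks, need %d distinct",
              nrow(probe_ts$tasks), 2L * design$trials_per_block)
      probe_rows <- sample(nrow(probe_ts$tasks))
      p1_rows <- probe_rows[seq_len(design$trials_per_block)]
      p2_rows <- probe_rows[design$trials_per_block +
                              seq_len(design$trials_per_block)]
      for (bi in seq_along(design$block_labels)) {
        blk <- design$block_labels[bi]
        sess <- design$block_sessions[bi]
        if (blk %in% c("p1", "p2")) {
          ts <- probe_ts
          rows <- if (blk == "p1") p1_rows else p2_rows
        } else {
          ts <- train_ts
          ti <- as.integer(sub("t", "", blk))
          # recycle the permutation when emulating with a reduced taskset
          idx <- ((ti - 1L) * design$trials_per_block +
                    seq_len(design$trials_per_block) - 1L) %%
            length(train_order) + 1L
          rows <- train_order[idx]
        }
        for (r in rows) {
          tk <- ts$tasks[r, ]
          task <- list(start = tk$start, goal = tk$goal,
                       ruleset_id = ts$ruleset$id)
          g <- graphs[[.graph_key(tk$start, tk$goal)]]
          trials[[length(trials) + 1L]] <-
            simulate_trial(agent, task, g, memory, participant = pid,
                           session = sess, block = blk, group = grp)
        }
        refit_agent_heuristic(memory, ts$ruleset$id)
        sr <- .strategy_report(agent)
        strat[[length(strat) + 1L]] <- data.frame(
          participant = pid, session = sess, block = blk,
          x = sr[["x"]], y = sr[["y"]], z = sr[["z"]],
          stringsAsFactors = FALSE)
        if (bi == length(design$block_labels) ||
            design$block_sessions[bi + 1L] != sess) {
          # each length 12..21 twice per session, in random order
          lens <- sample(rep(12:21, 2L))
          lens <- lens[seq_len(min(length(lens),
                                   design$wm_trials_per_session))]
          for (L in lens) {
            o <- .simulate_wm_trial(agent, L)
            wm[[length(wm) + 1L]] <- list(participant = pid,
                                          session = sess,
                                          sequence = o$sequence,
                                          response = o$response)
          }
        }
      }
    }
    list(trials = trials, wm = wm, strategy = do.call(rbind, strat),
         graphs = graphs, design = design,
         transfer_enabled = isTRUE(transfer_enabled))
  })
}

#' Write a simulated cohort dataset to disk
#'
#' Emits the event log as JSON-Lines plus strategy-report and
#' working-memory CSV tables.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_event_log(cohort$trials, file.path(dir, "trials.jsonl"))
  utils::write.csv(cohort$strategy, file.path(dir, "strategy.csv"),
                   row.names = FALSE)
  wm <- do.call(rbind, lapply(cohort$wm, function(w)
    data.frame(participant = w$participant, session = w$session,
               sequence = w$sequence, response = w$response,
               stringsAsFactors = FALSE)))
  utils::write.csv(wm, file.path(dir, "wm.csv"), row.names = FALSE)
  invisible(dir)
}
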