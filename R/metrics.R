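#' Construct a trial record
#'
#' A trial record holds the timestamped event stream of one problem-solving
#' trial plus its outcome. Events are a data.frame with columns `t`
#' (seconds from trial start, non-decreasing), `kind` (one of
#' `rule_activate`, `rule_deactivate`, `symbol_activate`,
#' `symbol_deactivate`, `state_change`, `undo`, `reset`, `click`), and
#' payload columns `rule`, `pos`, `state`, `x`, `y` (NA where not
#' applicable).
#'
#' @param participant Participant id.
#' @param session Session number (1-4).
#' @param block Block label (`p1`, `t1` .. `t6`, `p2`).
#' @param task List with `start`, `goal`, `ruleset_id`.
#' @param events Event data.frame as described above.
#' @param solved Logical outcome flag.
#' @param steps Number of successful rule applications.
#' @param score Integer trial score (0 when unsolved).
#' @param group Counterbalance group label (optional).
#' @return A list of class `trial_record`.
#' @export
trial_record <- function(participant, session, block, task, events,
                         solved, steps = sum(events$kind == "state_change"),
                         score = 0L, group = NA_character_) {
  if (is.unsorted(events$t)) stopf("event timestamps must be non-decreasing")
  structure(list(participant = participant, session = as.integer(session),
                 block = block, task = task, events = events,
                 solved = isTRUE(solved), steps = as.integer(steps),
                 score = as.integer(score), group = group),
            class = "trial_record")
}

empty_events <- function() {
  data.frame(t = numeric(0), kind = character(0), rule = integer(0),
             pos = integer(0), state = character(0), x = numeric(0),
             y = numeric(0), stringsAsFactors = FALSE)
}

#' Extract rule-application attempts from a trial's event stream
#'
#' An attempt is a maximal pair of one rule-activation and one
#' symbol-activation event, in either order. An attempt is valid when a
#' state change immediately follows the completed pair. Two successive
#' activations of the same kind discard the earlier one with a warning.
#'
#' @param trial A [trial_record()].
#' @return Data frame with one row per attempt: `rule`, `pos`, `valid`,
#'   `t_start`, `t_end`, and the click coordinates of the two events
#'   (`x1`, `y1`, `x2`, `y2`).
#' @export
extract_attempts <- function(trial) {
  ev <- trial$events
  out <- list()
  pending <- NULL
  n <- nrow(ev)
  for (i in seq_len(n)) {
    kind <- ev$kind[i]
    if (!(kind %in% c("rule_activate", "symbol_activate"))) next
    if (is.null(pending)) {
      pending <- i
    } else if (ev$kind[pending] == kind) {
      warning(sprintf(
        "discarding unpaired %s at t=%.3f (followed by another)",
        ev$kind[pending], ev$t[pending]), call. = FALSE)
      pending <- i
    } else {
      ri <- if (kind == "rule_activate") i else pending
      si <- if (kind == "symbol_activate") i else pending
      nxt <- i + 1L
      while (nxt <= n && ev$kind[nxt] %in% c("rule_deactivate",
                                             "symbol_deactivate"))
        nxt <- nxt + 1L
      out[[length(out) + 1L]] <- data.frame(
        rule = ev$rule[ri], pos = ev$pos[si],
        valid = nxt <= n && ev$kind[nxt] == "state_change",
        t_start = ev$t[pending], t_end = ev$t[i],
        x1 = ev$x[pending], y1 = ev$y[pending],
        x2 = ev$x[i], y2 = ev$y[i])
      pending <- NULL
    }
  }
  if (!is.null(pending))
    warning(sprintf("discarding unpaired %s at t=%.3f (end of trial)",
                    ev$kind[pending], ev$t[pending]), call. = FALSE)
  if (!length(out))
    return(data.frame(rule = integer(0), pos = integer(0),
                      valid = logical(0), t_start = numeric(0),
                      t_end = numeric(0), x1 = numeric(0), y1 = numeric(0),
                      x2 = numeric(0), y2 = numeric(0)))
  do.call(rbind, out)
}

#' Time between successive rule-use attempts
#'
#' The default convention measures idle/decision time between completed
#' attempts: the difference between the start of attempt `k + 1` and the
#' end of attempt `k`. The alternative `"end_to_end"` convention differences
#' the pair-end times of consecutive attempts.
#'
#' @param trial A [trial_record()].
#' @param mode `"gap"` (default) or `"end_to_end"`.
#' @return Numeric vector of intervals in seconds (empty with fewer than
#'   two attempts).
#' @export
between_rule_times <- function(trial, mode = c("gap", "end_to_end")) {
  mode <- match.arg(mode)
  at <- extract_attempts(trial)
  n <- nrow(at)
  if (n < 2L) return(numeric(0))
  if (mode == "gap") at$t_start[-1L] - at$t_end[-n] else diff(at$t_end)
}

#' Mean cursor speed during rule-use attempts
#'
#' Cursor movements are assumed to follow straight lines between the click
#' coordinates of the two events of each attempt; the attempt's speed is
#' that distance divided by the time between the clicks, and the trial
#' value is the mean over attempts. Zero time deltas are skipped with a
#' warning.
#'
#' @param trial A [trial_record()].
#' @return Mean speed in pixels/second (NA with no usable attempt).
#' @export
cursor_speed <- function(trial) {
  at <- extract_attempts(trial)
  if (!nrow(at)) return(NA_real_)
  dt <- at$t_end - at$t_start
  keep <- is.finite(dt) & dt > 0 & !is.na(at$x1) & !is.na(at$x2)
  if (any(dt == 0, na.rm = TRUE))
    warning("skipping attempt with zero time between clicks", call. = FALSE)
  if (!any(keep)) return(NA_real_)
  d <- sqrt((at$x2 - at$x1)^2 + (at$y2 - at$y1)^2)
  mean(d[keep] / dt[keep])
}

#' Reconstruct the state trajectory of a trial
#'
#' Replays `state_change`, `undo`, and `reset` events to give the current
#' state after every change, starting from the task's start state at t = 0.
#'
#' @param trial A [trial_record()].
#' @return Data frame with columns `t` and `state`.
#' @export
trial_states <- function(trial) {
  ev <- trial$events
  stack <- trial$task$start
  t_out <- 0
  s_out <- trial$task$start
  for (i in seq_len(nrow(ev))) {
    kind <- ev$kind[i]
    if (kind == "state_change") {
      stack <- c(stack, ev$state[i])
    } else if (kind == "undo") {
      if (length(stack) > 1L) stack <- stack[-length(stack)]
    } else if (kind == "reset") {
      stack <- stack[1L]
    } else next
    t_out <- c(t_out, ev$t[i])
    s_out <- c(s_out, stack[length(stack)])
  }
  data.frame(t = t_out, state = s_out, stringsAsFactors = FALSE)
}

.graph_key <- function(start, goal) paste(start, goal, sep = " -> ")

#' Build the per-task state graphs needed by [optimality_stats()]
#'
#' @param trials List of [trial_record()] objects.
#' @param ruleset_list Named list of [ruleset()] objects keyed by
#'   `ruleset_id`.
#' @param caps [graph_caps()] for enumeration.
#' @return Named list of [state_graph()] objects keyed by
#'   `"start -> goal"`.
#' @export
task_graphs <- function(trials, ruleset_list,
                        caps = graph_caps(max_depth = 40L,
                                          max_nodes = 4000L)) {
  out <- list()
  for (tr in trials) {
    key <- .graph_key(tr$task$start, tr$task$goal)
    if (is.null(out[[key]]))
      out[[key]] <- state_graph(tr$task$start, tr$task$goal,
                                ruleset_list[[tr$task$ruleset_id]],
                                caps = caps)
  }
  out
}

#' Action-sequence optimality / efficiency statistics
#'
#' Two related measures over the states visited during trials:
#'
#' * `minimal_distance`: for each state visited in a solved trial, the
#'   remaining number of successful rule applications is compared with the
#'   state's minimal distance to the goal; a visit is optimal when they are
#'   equal. Only solved trials contribute.
#' * `median_group`: states are grouped by their median remaining solution
#'   length (over all acyclic solution paths); the observed remaining
#'   length counts every attempt, valid or invalid, ignoring undo and reset
#'   events, and a visit meets the criterion when the trial was solved and
#'   the observed length is no greater than the group median. Unsolved
#'   trials count as failures for every state they visit.
#'
#' @param trials List of [trial_record()] objects.
#' @param graphs Output of [task_graphs()] covering every trial's task.
#' @param mode `"minimal_distance"` or `"median_group"`.
#' @return Data frame with columns `participant`, `block`, `distance`,
#'   `n`, `n_optimal`.
#' @export
optimality_stats <- function(trials, graphs,
                             mode = c("minimal_distance", "median_group")) {
  mode <- match.arg(mode)
  rows <- list()
  med_cache <- new.env(parent = emptyenv())
  for (tr in trials) {
    g <- graphs[[.graph_key(tr$task$start, tr$task$goal)]]
    if (is.null(g)) stopf("no graph for task %s -> %s", tr$task$start,
                          tr$task$goal)
    states <- trial_states(tr)
    if (mode == "minimal_distance") {
      if (!tr$solved) next
      napply <- sum(tr$events$kind == "state_change")
      applied_before <- vapply(states$t, function(tt)
        sum(tr$events$kind == "state_change" & tr$events$t <= tt),
        numeric(1))
      remaining <- napply - applied_before
      dist <- vapply(states$state, function(s) {
        d <- g$dist[s]
        if (is.na(d)) d <- .distance_on_demand(s, g)
        unname(d)
      }, numeric(1))
      keep <- dist >= 1 & is.finite(dist)
      if (!any(keep)) next
      rows[[length(rows) + 1L]] <- data.frame(
        participant = tr$participant, block = tr$block,
        distance = dist[keep], optimal = remaining[keep] == dist[keep])
    } else {
      at <- suppressWarnings(extract_attempts(tr))
      for (i in seq_len(nrow(states))) {
        s <- states$state[i]
        if (s == tr$task$goal) next
        mkey <- paste(.graph_key(tr$task$start, tr$task$goal), s,
                      sep = "\r")
        m <- med_cache[[mkey]]
        if (is.null(m)) {
          m <- median_remaining_solution_length(s, g)
          assign(mkey, m, envir = med_cache)
        }
        observed <- sum(at$t_start > states$t[i] |
                          (states$t[i] == 0 & at$t_start >= 0))
        ok <- tr$solved && observed <= m
        rows[[length(rows) + 1L]] <- data.frame(
          participant = tr$participant, block = tr$block, distance = m,
          optimal = ok)
      }
    }
  }
  if (!length(rows))
    return(data.frame(participant = character(0), block = character(0),
                      distance = numeric(0), n = integer(0),
                      n_optimal = integer(0)))
  d <- do.call(rbind, rows)
  agg <- aggregate(cbind(n = rep(1L, nrow(d)), n_optimal = d$optimal),
                   by = list(participant = d$participant, block = d$block,
                             distance = d$distance), FUN = sum)
  agg[order(agg$participant, agg$block, agg$distance), ]
}

# States reached via undo divergence may be missing from the forward graph;
# recompute their distance by a fresh bounded enumeration.
.distance_on_demand <- function(state, graph) {
  g2 <- state_graph(state, graph$goal, graph$ruleset, caps = graph$caps)
  g2$dist[[state]]
}

#' Convert pairwise strategy preferences to strategy weights
#'
#' Converts the three pairwise preference proportions reported after each
#' block into weights for the three strategies. `x` is the preference for
#' "try-and-see" over "work-it-out", `y` for "work-it-out" over
#' "intuition", and `z` for "intuition" over "try-and-see". The conversion
#' uses only `x` and `y`; `z` is retained as a redundancy/consistency
#' check. Inputs of exactly 0 or 1 are clamped to 0.01/0.99 (with a
#' warning), matching the assumption that preferences are non-extreme.
#' The three weights always sum to 1.
#'
#' @param x,y,z Proportions in `[0, 1]`; vectors are accepted.
#' @return Data frame with columns `w_t` (try-and-see), `w_w`
#'   (work-it-out), `w_i` (intuition).
#' @examples
#' strategy_weights(0.5, 0.5)  # 1/3, 1/3, 1/3
#' @export
strategy_weights <- function(x, y, z = NULL) {
  clamp <- function(v) {
    if (any(v <= 0 | v >= 1, na.rm = TRUE))
      warning("extreme preference values clamped to [0.01, 0.99]",
              call. = FALSE)
    pmin(pmax(v, 0.01), 0.99)
  }
  x <- clamp(x); y <- clamp(y)
  w_t <- x * y / (1 - x + x * y)
  w_w <- w_t * (1 - x) / x
  w_i <- w_w * (1 - y) / y
  data.frame(w_t = w_t, w_w = w_w, w_i = w_i)
}

#' Per-offset recall correctness for a running-span trial
#'
#' The typed response is aligned against the tail of the shown sequence:
#' the digit at offset `k` (counting from the end, offset 0 = final digit)
#' is correct when the response's k-th-from-last digit equals the
#' sequence's k-th-from-last digit. Offsets beyond the typed response are
#' incorrect.
#'
#' @param sequence,response Digit strings.
#' @return Data frame with columns `offset` (0-based) and `correct`.
#' @export
wm_correct_by_offset <- function(sequence, response) {
  seq_ch <- rev(strsplit(sequence, "")[[1]])
  resp_ch <- if (nchar(response %||% "") > 0)
    rev(strsplit(response, "")[[1]]) else character(0)
  n <- length(seq_ch)
  correct <- logical(n)
  k <- min(n, length(resp_ch))
  if (k > 0) correct[seq_len(k)] <- seq_ch[seq_len(k)] == resp_ch[seq_len(k)]
  data.frame(offset = 0:(n - 1L), correct = correct)
}

# Logistic fit of correctness on offset, with degenerate-data handling.
.wm_fit <- function(offsets, correct) {
  if (all(correct)) return(list(kind = "all_correct"))
  if (!any(correct)) return(list(kind = "all_wrong"))
  fit <- suppressWarnings(glm(correct ~ offsets, family = binomial()))
  b <- coef(fit)
  if (anyNA(b)) return(list(kind = "degenerate"))
  list(kind = "ok", b0 = unname(b[1]), b1 = unname(b[2]))
}

#' Working-memory score from running-span outcomes
#'
#' Fits a logistic regression of per-offset recall correctness on offset
#' (offset 0 = final digit) and finds the offset at which the fitted recall
#' probability drops to the chance level of 1/9 (digits "1" to "9"). The
#' score is that crossing point, clamped to the observed offset range, plus
#' one. Degenerate data are flagged: a non-decreasing recall curve or
#' all-correct responses score `max offset + 1`; all-wrong responses score
#' 1.
#'
#' @param outcomes List of lists with elements `sequence` and `response`
#'   (one participant-session's trials), or a data.frame with those
#'   columns.
#' @return Numeric score with attribute `flag` (`"ok"` or the degeneracy
#'   kind).
#' @export
wm_score <- function(outcomes) {
  if (is.data.frame(outcomes))
    outcomes <- lapply(seq_len(nrow(outcomes)), function(i)
      list(sequence = outcomes$sequence[i], response = outcomes$response[i]))
  if (!length(outcomes)) stopf("at least one outcome is required")
  tab <- do.call(rbind, lapply(outcomes, function(o)
    wm_correct_by_offset(o$sequence, o$response)))
  max_offset <- max(tab$offset)
  fit <- .wm_fit(tab$offset, tab$correct)
  chance <- qlogis(1 / 9)
  score <- switch(fit$kind,
    all_correct = max_offset + 1,
    all_wrong = 1,
    degenerate = max_offset + 1,
    ok = {
      if (fit$b1 >= 0) {
        fit$kind <- "nondecreasing"
        max_offset + 1
      } else {
        o_star <- (chance - fit$b0) / fit$b1
        min(max(o_star, 0), max_offset) + 1
      }
    })
  structure(score, flag = if (fit$kind == "ok") "ok" else fit$kind)
}

# Fitted recall probability at offset 0 for one participant-session.
.wm_offset0_prob <- function(outcomes) {
  tab <- do.call(rbind, lapply(outcomes, function(o)
    wm_correct_by_offset(o$sequence, o$response)))
  fit <- .wm_fit(tab$offset, tab$correct)
  switch(fit$kind,
         all_correct = 1,
         all_wrong = 0,
         degenerate = mean(tab$correct[tab$offset == 0]),
         ok = expit(fit$b0))
}

#' Apply the cohort exclusion criteria
#'
#' A participant is retained when, in every one of the four sessions, they
#' solved at least one problem-solving trial and recalled the final digit
#' of the running-span sequences with probability above chance (1/9,
#' assessed at offset 0 of the per-session logistic recall fit).
#' Participants with missing sessions are excluded with reason
#' `"incomplete"`.
#'
#' @param trials List of [trial_record()] objects for the whole cohort.
#' @param wm List of working-memory outcome records, each with
#'   `participant`, `session`, `sequence`, `response`.
#' @param n_sessions Number of sessions required (default 4).
#' @return List with `included` (character vector of participant ids) and
#'   `report` (data.frame `participant`, `excluded`, `reason`).
#' @export
apply_exclusions <- function(trials, wm, n_sessions = 4L) {
  pid <- vapply(trials, function(tr) as.character(tr$participant),
                character(1))
  sess <- vapply(trials, function(tr) tr$session, integer(1))
  solved <- vapply(trials, function(tr) tr$solved, logical(1))
  wm_pid <- vapply(wm, function(w) as.character(w$participant), character(1))
  wm_sess <- vapply(wm, function(w) as.integer(w$session), integer(1))
  participants <- sort(unique(c(pid, wm_pid)))
  report <- data.frame(participant = participants, excluded = FALSE,
                       reason = "", stringsAsFactors = FALSE)
  for (i in seq_along(participants)) {
    p <- participants[i]
    psess <- sort(unique(sess[pid == p]))
    wsess <- sort(unique(wm_sess[wm_pid == p]))
    if (!all(seq_len(n_sessions) %in% psess) ||
        !all(seq_len(n_sessions) %in% wsess)) {
      report$excluded[i] <- TRUE
      report$reason[i] <- "incomplete"
      next
    }
    solves <- vapply(seq_len(n_sessions), function(s)
      any(solved[pid == p & sess == s]), logical(1))
    if (!all(solves)) {
      report$excluded[i] <- TRUE
      report$reason[i] <- "no solve in every session"
      next
    }
    p0 <- vapply(seq_len(n_sessions), function(s)
      .wm_offset0_prob(wm[wm_pid == p & wm_sess == s]), numeric(1))
    if (!all(p0 > 1 / 9)) {
      report$excluded[i] <- TRUE
      report$reason[i] <- "final-digit recall at or below chance"
    }
  }
  list(included = report$participant[!report$excluded], report = report)
}

#' Per-participant, per-block summary measures
#'
#' @param trials List of [trial_record()] objects.
#' @return Data frame with one row per participant and block: trial and
#'   solve counts, solved proportion, mean between-rule time, mean cursor
#'   speed, mean score, session, and group.
#' @export
block_measures <- function(trials) {
  rows <- lapply(trials, function(tr) {
    brt <- suppressWarnings(between_rule_times(tr))
    data.frame(participant = as.character(tr$participant),
               session = tr$session, block = tr$block,
               group = tr$group %||% NA_character_,
               solved = tr$solved, score = tr$score,
               mean_brt = if (length(brt)) mean(brt) else NA_real_,
               cursor = suppressWarnings(cursor_speed(tr)),
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  d$group[is.na(d$group)] <- "unknown"
  agg <- aggregate(
    cbind(n_trials = rep(1L, nrow(d)), n_solved = d$solved),
    by = list(participant = d$participant, session = d$session,
              block = d$block, group = d$group), FUN = sum)
  means <- aggregate(
    cbind(mean_brt = d$mean_brt, mean_cursor = d$cursor,
          mean_score = d$score),
    by = list(participant = d$participant, session = d$session,
              block = d$block, group = d$group),
    FUN = function(v) mean(v, na.rm = TRUE))
  out <- merge(agg, means,
               by = c("participant", "session", "block", "group"))
  out$prop_solved <- out$n_solved / out$n_trials
  out[order(out$participant, out$session, out$block), ]
}

#' Write trial records as JSON-Lines
#'
#' One trial per line, with the event table nested under `events`.
#'
#' @param trials List of [trial_record()] objects.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_event_log <- function(trials, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (tr in trials) {
    obj <- unclass(tr)
    writeLines(jsonlite::toJSON(obj, dataframe = "columns",
                                auto_unbox = TRUE, digits = NA,
                                na = "null"), con)
  }
  invisible(path)
}

#' Read trial records from JSON-Lines
#'
#' @param path File written by [write_event_log()].
#' @return List of [trial_record()] objects.
#' @export
read_event_log <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    ev <- as.data.frame(obj$events, stringsAsFactors = FALSE)
    if (!nrow(ev)) ev <- empty_events()
    trial_record(obj$participant, obj$session, obj$block, obj$task, ev,
                 obj$solved, obj$steps, obj$score,
                 obj$group %||% NA_character_)
  })
}
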