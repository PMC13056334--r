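#' Create a rewrite rule
#'
#' A rule replaces an occurrence of its left-hand side, matched at a clicked
#' position of the current state string, with its right-hand side. Both sides
#' are non-empty strings of single-character symbols.
#'
#' @param id Small integer identifier, unique within a ruleset.
#' @param lhs,rhs Non-empty symbol strings.
#' @return An object of class `rw_rule`.
#' @examples
#' rule(1, "AB", "C")
#' @export
rule <- function(id, lhs, rhs) {
  assert_string1(lhs, "lhs")
  assert_string1(rhs, "rhs")
  structure(list(id = as.integer(id), lhs = lhs, rhs = rhs),
            class = "rw_rule")
}

#' @export
print.rw_rule <- function(x, ...) {
  cat(sprintf("rule %d: %s -> %s\n", x$id, x$lhs, x$rhs))
  invisible(x)
}

#' Create a ruleset
#'
#' A ruleset is an ordered collection of rewrite rules over a symbol
#' alphabet. Study-grade rulesets contain exactly five rules; this
#' constructor accepts any positive number so small fixtures can be built.
#'
#' @param rules List of [rule()] objects (or a data.frame with columns
#'   `id`, `lhs`, `rhs`).
#' @param id Label for the ruleset.
#' @param alphabet Optional character vector of symbols; defaults to the
#'   symbols appearing in the rules.
#' @return An object of class `ruleset` with fields `id`, `ids`, `lhs`,
#'   `rhs`, `alphabet`.
#' @examples
#' ruleset(list(rule(1, "A", "B"), rule(2, "BB", "A")), id = "demo")
#' @export
ruleset <- function(rules, id = "rs", alphabet = NULL) {
  if (is.data.frame(rules)) {
    rules <- lapply(seq_len(nrow(rules)), function(i)
      rule(rules$id[i], rules$lhs[i], rules$rhs[i]))
  }
  if (length(rules) == 0L) stopf("ruleset needs at least one rule")
  ids <- vapply(rules, function(r) r$id, integer(1))
  if (anyDuplicated(ids)) stopf("rule ids must be unique")
  lhs <- vapply(rules, function(r) r$lhs, character(1))
  rhs <- vapply(rules, function(r) r$rhs, character(1))
  eff <- sort(unique(unlist(strsplit(c(lhs, rhs), ""))))
  if (is.null(alphabet)) alphabet <- eff
  if (!all(eff %in% alphabet)) stopf("rules use symbols outside the alphabet")
  structure(list(id = id, ids = ids, lhs = lhs, rhs = rhs,
                 alphabet = alphabet),
            class = "ruleset")
}

#' @export
print.ruleset <- function(x, ...) {
  cat(sprintf("ruleset '%s' (%d rules, alphabet {%s})\n", x$id,
              length(x$ids), paste(x$alphabet, collapse = "")))
  for (i in seq_along(x$ids))
    cat(sprintf("  %d: %s -> %s\n", x$ids[i], x$lhs[i], x$rhs[i]))
  invisible(x)
}

#' @export
length.ruleset <- function(x) length(x$ids)

#' Apply one rewrite rule at a position
#'
#' Positions are 0-based, matching the task convention in which the clicked
#' symbol indexes the start of the matched substring. A rule fits only if
#' `position + nchar(lhs) <= nchar(state)` and the substring at that span
#' equals the rule's left-hand side; otherwise the application is invalid (a
#' modelled in-task event, not an error) and `NA_character_` is returned.
#'
#' @param state Symbol string.
#' @param rule A [rule()] object.
#' @param position 0-based index into `state`; out-of-range positions are an
#'   argument error, distinct from an invalid application.
#' @return The rewritten string, or `NA_character_` for an invalid
#'   application.
#' @examples
#' apply_rule("XABY", rule(1, "AB", "C"), 1)  # "XCY"
#' apply_rule("XABY", rule(1, "AB", "C"), 0)  # NA (mismatch)
#' @export
apply_rule <- function(state, rule, position) {
  assert_string1(state, "state")
  res <- apply_rule_cpp(state, rule$lhs, rule$rhs, as.integer(position))
  if (is.na(res)) NA_character_ else res
}

#' Enumeration caps for state-graph construction
#'
#' Rewriting systems can grow without bound, so enumeration is always capped
#' and the resulting graph records whether any cap bound the search.
#'
#' @param max_depth Maximum breadth-first depth from the start state.
#' @param max_len Maximum string length retained; `NULL` means
#'   `2 * max(nchar(start), nchar(goal), 8)`.
#' @param max_nodes Maximum number of distinct states.
#' @return A list of class `graph_caps`.
#' @export
graph_caps <- function(max_depth = 10L, max_len = NULL, max_nodes = 200000L) {
  structure(list(max_depth = as.integer(max_depth),
                 max_len = if (is.null(max_len)) NULL else as.integer(max_len),
                 max_nodes = as.integer(max_nodes)),
            class = "graph_caps")
}

#' Enumerate the reachable state graph of a task
#'
#' Breadth-first enumeration of all states reachable from `start` under the
#' ruleset, subject to [graph_caps()]. Each edge is a single valid rule
#' application labelled `(rule id, 0-based position)`. Distances to the goal
#' are computed by reverse breadth-first search over the enumerated edges;
#' states with no path to the goal get distance `Inf`.
#'
#' @param start,goal Symbol strings.
#' @param ruleset A [ruleset()].
#' @param caps A [graph_caps()] object.
#' @return An object of class `state_graph` with fields `nodes`, `edges`
#'   (data.frame `from`, `rule`, `pos`, `to`), `start`, `goal`, `depth`
#'   (distance from start), `dist` (distance to goal, `Inf` allowed), and
#'   `truncated`.
#' @examples
#' g <- state_graph("AA", "BB", ruleset(list(rule(1, "A", "B"))))
#' g$dist[["AA"]]  # 2
#' @export
state_graph <- function(start, goal, ruleset, caps = graph_caps()) {
  assert_string1(start, "start")
  assert_string1(goal, "goal")
  max_len <- caps$max_len %||% (2L * max(nchar(start), nchar(goal), 8L))
  enum <- enumerate_cpp(start, ruleset$lhs, ruleset$rhs,
                        as.integer(caps$max_depth), as.integer(max_len),
                        as.integer(caps$max_nodes))
  nodes <- enum$nodes
  depth <- enum$depth
  goal_idx <- match(goal, nodes)
  goal_unreachable <- is.na(goal_idx)
  if (goal_unreachable) {
    nodes <- c(nodes, goal)
    depth <- c(depth, NA_integer_)
    goal_idx <- length(nodes)
  }
  dist_int <- reverse_bfs_cpp(length(nodes), enum$ef, enum$et, goal_idx)
  dist <- as.numeric(dist_int)
  dist[is.na(dist)] <- Inf
  names(dist) <- nodes
  names(depth) <- nodes
  edges <- data.frame(from = nodes[enum$ef],
                      rule = ruleset$ids[enum$er],
                      pos = enum$ep,
                      to = nodes[enum$et],
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, start = start,
                 goal = goal, depth = depth, dist = dist,
                 truncated = enum$truncated,
                 goal_unreachable = goal_unreachable,
                 ruleset = ruleset, caps = caps,
                 ef = enum$ef, er = enum$er, ep = enum$ep, et = enum$et),
            class = "state_graph")
}

#' @export
print.state_graph <- function(x, ...) {
  cat(sprintf("state graph: %d states, %d edges; start '%s' -> goal '%s'\n",
              length(x$nodes), nrow(x$edges), x$start, x$goal))
  cat(sprintf("  distance(start) = %s; truncated = %s\n",
              format(x$dist[[x$start]]), x$truncated))
  invisible(x)
}

# Adjacency list of edge-row indices keyed by from-state, built lazily.
.adjacency <- function(graph) {
  split(seq_len(nrow(graph$edges)), factor(graph$edges$from,
                                           levels = graph$nodes))
}

#' Count minimal solution sequences
#'
#' Counts distinct action sequences of length exactly
#' `distance_to_goal(start)` from the start to the goal. Two sequences are
#' distinct if they differ at any step in rule id, position, or intermediate
#' state. When `start == goal` the single empty sequence is counted.
#' With `minimal_only = FALSE`, all acyclic solution sequences of length at
#' most `length_cap` are counted instead.
#'
#' @param graph A [state_graph()].
#' @param minimal_only Count only minimal-length sequences (default) or all
#'   acyclic sequences up to `length_cap`.
#' @param length_cap Length bound used when `minimal_only = FALSE`; defaults
#'   to `dist(start) + 6`.
#' @return Positive integer count.
#' @export
count_minimal_solutions <- function(graph, minimal_only = TRUE,
                                    length_cap = NULL) {
  d0 <- graph$dist[[graph$start]]
  if (is.infinite(d0)) stopf("goal is not reachable from the start state")
  if (!minimal_only) {
    cap <- length_cap %||% (d0 + 6)
    lens <- all_solution_lengths(graph$start, graph, path_cap = cap)
    return(length(lens))
  }
  if (d0 == 0) return(1L)
  di <- unname(graph$dist)
  ef <- graph$ef; et <- graph$et
  on_step <- is.finite(di[ef]) & is.finite(di[et]) & di[et] == di[ef] - 1
  ef <- ef[on_step]; et <- et[on_step]
  counts <- numeric(length(graph$nodes))
  counts[match(graph$goal, graph$nodes)] <- 1
  for (d in seq_len(d0)) {
    sel <- which(di[ef] == d)
    if (length(sel)) {
      contrib <- rowsum(counts[et[sel]], ef[sel])
      counts[as.integer(rownames(contrib))] <- contrib[, 1L]
    }
  }
  as.integer(counts[match(graph$start, graph$nodes)])
}

#' Lengths of all acyclic action sequences from a state to the goal
#'
#' Depth-first enumeration of acyclic (no repeated state) paths from `state`
#' to the graph's goal, up to `path_cap` steps.
#'
#' @param state A state in the graph.
#' @param graph A [state_graph()].
#' @param path_cap Maximum path length considered.
#' @return Integer vector of path lengths (possibly empty).
#' @export
all_solution_lengths <- function(state, graph, path_cap) {
  node_id <- seq_along(graph$nodes)
  names(node_id) <- graph$nodes
  if (is.na(node_id[state])) stopf("state '%s' is not in the graph", state)
  adj <- .adjacency(graph)
  to_id <- node_id[graph$edges$to]
  goal_id <- node_id[[graph$goal]]
  lens <- integer(0)
  visited <- logical(length(graph$nodes))
  rec <- function(v, len) {
    if (v == goal_id) {
      lens[[length(lens) + 1L]] <<- len
      return(invisible())
    }
    if (len >= path_cap) return(invisible())
    visited[v] <<- TRUE
    for (e in adj[[v]]) {
      w <- to_id[e]
      if (!visited[w]) rec(w, len + 1L)
    }
    visited[v] <<- FALSE
    invisible()
  }
  rec(node_id[[state]], 0L)
  lens
}

#' Median remaining solution length from a state
#'
#' The median length of all acyclic action sequences from `state` to the
#' goal, bounded by `path_cap`; `Inf` when no such sequence exists. Used to
#' group states for the action-sequence efficiency measure.
#'
#' @inheritParams all_solution_lengths
#' @param path_cap Maximum path length; defaults to
#'   `distance_to_goal(state) + 6`.
#' @return A number, or `Inf` for dead-end states.
#' @export
median_remaining_solution_length <- function(state, graph, path_cap = NULL) {
  d <- graph$dist[[state]]
  if (is.null(d)) stopf("state '%s' is not in the graph", state)
  if (is.infinite(d)) return(Inf)
  cap <- path_cap %||% (d + 6)
  lens <- all_solution_lengths(state, graph, path_cap = cap)
  if (!length(lens)) return(Inf)
  median(lens)
}

#' Does the graph contain a commutative transition?
#'
#' TRUE when some state can be reached from a common ancestor by applying
#' the same two rule applications (rule id and position) in either order.
#' Task generation rejects graphs with this property.
#'
#' @param graph A [state_graph()].
#' @return Logical flag.
#' @export
has_commutative_transition <- function(graph) {
  if (!length(graph$ef)) return(FALSE)
  commutative_cpp(length(graph$nodes), graph$ef, graph$er, graph$ep,
                  graph$et)
}

#' Is a wrong turn available everywhere on the solution paths?
#'
#' TRUE iff every non-goal state lying on at least one minimal solution path
#' has at least one successor that is not on any minimal solution path from
#' that state (i.e., a successor whose distance to the goal is not one less
#' than the state's). Task generation requires this so solvers can take a
#' wrong turn at any point.
#'
#' @param graph A [state_graph()].
#' @return Logical flag (vacuously TRUE when start equals goal).
#' @export
wrong_turn_everywhere <- function(graph) {
  d0 <- graph$dist[[graph$start]]
  if (is.infinite(d0)) stopf("goal is not reachable from the start state")
  dist <- graph$dist
  depth <- graph$depth
  on_path <- names(dist)[!is.na(depth) & is.finite(dist) &
                           depth + dist == d0]
  on_path <- setdiff(on_path, graph$goal)
  if (!length(on_path)) return(TRUE)
  dist_to <- dist[graph$et]
  from_state <- graph$nodes[graph$ef]
  for (u in on_path) {
    out <- which(from_state == u)
    if (!length(out)) return(FALSE)
    if (!any(dist_to[out] != dist[[u]] - 1)) return(FALSE)
  }
  TRUE
}

#' Are two rulesets isomorphic under symbol relabelling?
#'
#' TRUE iff some bijection between the effective alphabets maps the multiset
#' of rules of `a` onto that of `b` (left-hand sides onto left-hand sides
#' and right-hand sides onto right-hand sides). Study-grade ruleset pairs
#' must NOT be isomorphic, so that neither can be recreated from the other
#' by substituting symbols.
#'
#' @param a,b [ruleset()] objects.
#' @return Logical flag.
#' @export
rulesets_isomorphic <- function(a, b) {
  if (length(a$ids) != length(b$ids)) return(FALSE)
  alpha_a <- sort(unique(unlist(strsplit(c(a$lhs, a$rhs), ""))))
  alpha_b <- sort(unique(unlist(strsplit(c(b$lhs, b$rhs), ""))))
  if (length(alpha_a) != length(alpha_b)) return(FALSE)
  prof_a <- sort(paste(nchar(a$lhs), nchar(a$rhs)))
  prof_b <- sort(paste(nchar(b$lhs), nchar(b$rhs)))
  if (!identical(prof_a, prof_b)) return(FALSE)
  target <- sort(paste(b$lhs, b$rhs, sep = ">"))
  k <- length(alpha_a)
  perm_check <- function(perm) {
    map <- setNames(alpha_b[perm], alpha_a)
    tr <- function(s) {
      vapply(strsplit(s, ""), function(ch)
        paste(map[ch], collapse = ""), character(1))
    }
    identical(sort(paste(tr(a$lhs), tr(a$rhs), sep = ">")), target)
  }
  found <- FALSE
  rec <- function(chosen, remaining) {
    if (found) return(invisible())
    if (!length(remaining)) {
      if (perm_check(chosen)) found <<- TRUE
      return(invisible())
    }
    for (i in seq_along(remaining)) {
      rec(c(chosen, remaining[i]), remaining[-i])
      if (found) return(invisible())
    }
    invisible()
  }
  rec(integer(0), seq_len(k))
  found
}

#' Export a state graph as an edge-list TSV
#'
#' @param graph A [state_graph()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_graph_tsv <- function(graph, path) {
  utils::write.table(graph$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE,
                     col.names = c("from_state", "rule_id", "position",
                                   "to_state"))
  invisible(path)
}
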