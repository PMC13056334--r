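.feature_names <- paste0("f", 1:13)

#' Compute the 13-feature representation of a (state, goal) pair
#'
#' The features quantify string properties usable by a rule-independent
#' state-value heuristic: positional match proportion (f1, denominator is
#' the state length, with positions past the shorter string counting as
#' mismatches), length difference (f2), unique-symbol count difference
#' (f3), longest-common-subsequence length as a proportion of the goal
#' length (f4), state/goal lengths (f5/f6), longest runs of repeated
#' symbols (f7/f8), shortest runs (f9/f10), run-collapsed lengths
#' (f11/f12), and the Levenshtein edit distance (f13). A lone symbol
#' counts as a run of length 1.
#'
#' @param state,goal Non-empty symbol strings.
#' @return Named numeric vector `f1` .. `f13`.
#' @examples
#' compute_features("AABBA", "ABC")
#' @export
compute_features <- function(state, goal) {
  assert_string1(state, "state")
  assert_string1(goal, "goal")
  setNames(as.numeric(feature_vector_cpp(state, goal)), .feature_names)
}

#' Feature matrix for many (state, goal) pairs
#'
#' @param states,goals Equal-length character vectors.
#' @return Numeric matrix with columns `f1` .. `f13`.
#' @export
feature_matrix <- function(states, goals) {
  m <- feature_matrix_cpp(as.character(states), as.character(goals))
  colnames(m) <- .feature_names
  m
}

.feature_subsets <- list(
  all = .feature_names,
  state_only = c("f5", "f7", "f9", "f11"),
  goal_only = c("f6", "f8", "f10", "f12"))

#' Label every enumerable state of a taskset by goal reachability
#'
#' For each task, enumerates all states reachable from the start and labels
#' each with ground-truth value 1 if the task's goal is reachable from it
#' and 0 otherwise. Pairs are de-duplicated on (state, goal). Truncated
#' enumerations are an error, never silently accepted.
#'
#' @param taskset A [generate_taskset()] result.
#' @param caps [graph_caps()] used for enumeration.
#' @return Data frame with columns `state`, `goal`, `value`.
#' @export
label_reachability <- function(taskset,
                               caps = graph_caps(max_depth = 40L,
                                                 max_nodes = 4000L)) {
  rs <- taskset$ruleset
  out <- vector("list", nrow(taskset$tasks))
  bad <- character(0)
  for (i in seq_len(nrow(taskset$tasks))) {
    tk <- taskset$tasks[i, ]
    g <- state_graph(tk$start, tk$goal, rs, caps = caps)
    if (g$truncated) {
      bad <- c(bad, sprintf("%s -> %s", tk$start, tk$goal))
      next
    }
    out[[i]] <- data.frame(state = g$nodes, goal = tk$goal,
                           value = as.integer(is.finite(g$dist)),
                           stringsAsFactors = FALSE)
  }
  if (length(bad))
    stopf("enumeration truncated for %d task(s): %s", length(bad),
          paste(head(bad, 5L), collapse = ", "))
  lab <- do.call(rbind, out)
  lab[!duplicated(paste(lab$state, lab$goal, sep = "\r")), , drop = FALSE]
}

#' Sample a class-balanced evaluation set of labelled states
#'
#' Uniform sampling without replacement of `n_pos` reachable and `n_neg`
#' unreachable (state, goal) pairs.
#'
#' @param labeled Output of [label_reachability()].
#' @param n_pos,n_neg Required counts per class (study emulation: 400/400).
#' @param seed Integer seed (optional).
#' @return Data frame of `n_pos + n_neg` rows with columns `state`, `goal`,
#'   `value` and the 13 feature columns.
#' @export
sample_balanced <- function(labeled, n_pos = 400L, n_neg = 400L,
                            seed = NULL) {
  pos <- which(labeled$value == 1L)
  neg <- which(labeled$value == 0L)
  if (length(pos) < n_pos || length(neg) < n_neg)
    stopf(paste0("insufficient labelled states: need %d positive and %d ",
                 "negative, have %d and %d"),
          n_pos, n_neg, length(pos), length(neg))
  with_seed(seed, {
    take <- c(sample(pos, n_pos), sample(neg, n_neg))
    out <- labeled[take, , drop = FALSE]
    rownames(out) <- NULL
    cbind(out, as.data.frame(feature_matrix(out$state, out$goal)))
  })
}

#' Fit the logistic state-value heuristic
#'
#' Fits `value ~ expit(beta0 + sum(beta_i * f_i))` by unpenalised maximum
#' likelihood on the selected feature subset. If the fit is perfectly
#' separated (non-converged or divergent coefficients), the model is refitted
#' with a tiny ridge penalty and flagged.
#'
#' @param data Data frame with a binary `value` column and feature columns.
#' @param feature_subset One of `"all"` (13 features), `"state_only"`
#'   (f5, f7, f9, f11), `"goal_only"` (f6, f8, f10, f12), or a character
#'   vector of feature names.
#' @return Object of class `svh_fit` with `coefficients`, `features`,
#'   `separation` flag.
#' @export
fit_state_value <- function(data, feature_subset = "all") {
  feats <- if (length(feature_subset) == 1L &&
               feature_subset %in% names(.feature_subsets)) {
    .feature_subsets[[feature_subset]]
  } else as.character(feature_subset)
  X <- as.matrix(data[, feats, drop = FALSE])
  y <- data$value
  fit <- suppressWarnings(glm.fit(cbind(`(Intercept)` = 1, X), y,
                                  family = binomial()))
  separated <- !fit$converged || any(abs(fit$coefficients) > 1e3,
                                     na.rm = TRUE) ||
    anyNA(fit$coefficients)
  se <- pval <- rep(NA_real_, length(fit$coefficients))
  if (!separated) {
    # Wald tests from the weighted cross-product at the optimum
    W <- fit$weights
    XtWX <- crossprod(cbind(1, X) * sqrt(W))
    cov <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (!is.null(cov)) {
      se <- sqrt(diag(cov))
      pval <- 2 * stats::pnorm(-abs(fit$coefficients / se))
    }
  } else {
    fit$coefficients <- .ridge_logistic(cbind(1, X), y, lambda = 1e-6)
  }
  structure(list(coefficients = setNames(fit$coefficients,
                                         c("(Intercept)", feats)),
                 se = se, p_values = pval, features = feats,
                 separation = separated, n = length(y)),
            class = "svh_fit")
}

# Small ridge-penalised logistic fit by iteratively reweighted least
# squares; fallback for perfectly separated data.
.ridge_logistic <- function(X, y, lambda = 1e-6, iter = 50L) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(iter)) {
    eta <- drop(X %*% beta)
    mu <- expit(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    A <- crossprod(X * sqrt(w)) + diag(lambda, ncol(X))
    beta_new <- solve(A, crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < 1e-8) { beta <- beta_new; break }
    beta <- beta_new
  }
  drop(beta)
}

#' @export
coef.svh_fit <- function(object, ...) object$coefficients

#' @export
predict.svh_fit <- function(object, newdata, type = c("response", "class"),
                            ...) {
  type <- match.arg(type)
  if (is.character(newdata$state) && !all(object$features %in%
                                          names(newdata))) {
    newdata <- cbind(newdata,
                     as.data.frame(feature_matrix(newdata$state,
                                                  newdata$goal)))
  }
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  p <- expit(drop(cbind(1, X) %*% object$coefficients))
  if (type == "response") p else as.integer(p > 0.5)
}

#' @export
print.svh_fit <- function(x, ...) {
  cat(sprintf("state-value heuristic fit (%d features, n = %d%s)\n",
              length(x$features), x$n,
              if (x$separation) ", ridge fallback" else ""))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Cross-validated transfer evaluation of the state-value heuristic
#'
#' Stratified k-fold cross-validation on the training evaluation set. For
#' each fold, the model is fitted to the remaining folds, its accuracy
#' (0.5 threshold) recorded on the held-out fold, and its generalisation
#' accuracy recorded on the entire transfer set. Reports median and
#' quartiles across folds plus per-fold coefficient tables with 1%-level
#' Wald significance flags.
#'
#' @param train,transfer Balanced evaluation sets from [sample_balanced()].
#' @param n_folds Number of folds (study emulation: 30).
#' @param feature_subset Passed to [fit_state_value()].
#' @param seed Integer seed controlling fold assignment.
#' @return Object of class `transfer_report`.
#' @export
evaluate_transfer <- function(train, transfer, n_folds = 30L,
                              feature_subset = "all", seed = NULL) {
  if (n_folds < 2L) stopf("n_folds must be >= 2")
  with_seed(seed, {
    folds <- integer(nrow(train))
    for (cl in unique(train$value)) {
      i <- which(train$value == cl)
      folds[i] <- sample(rep_len(seq_len(n_folds), length(i)))
    }
    test_acc <- gen_acc <- numeric(n_folds)
    coefs <- sig <- NULL
    any_sep <- FALSE
    for (k in seq_len(n_folds)) {
      fit <- fit_state_value(train[folds != k, , drop = FALSE],
                             feature_subset = feature_subset)
      any_sep <- any_sep || fit$separation
      held <- train[folds == k, , drop = FALSE]
      test_acc[k] <- mean(predict(fit, held, type = "class") == held$value)
      gen_acc[k] <- mean(predict(fit, transfer, type = "class") ==
                           transfer$value)
      if (is.null(coefs)) {
        coefs <- matrix(NA_real_, n_folds, length(fit$coefficients),
                        dimnames = list(NULL, names(fit$coefficients)))
        sig <- coefs
      }
      coefs[k, ] <- fit$coefficients
      sig[k, ] <- fit$p_values < 0.01
    }
    structure(list(
      feature_subset = if (length(feature_subset) == 1L) feature_subset
      else "custom",
      n_folds = n_folds,
      test_accuracy = quantile(test_acc, c(0.25, 0.5, 0.75), names = FALSE),
      generalisation_accuracy = quantile(gen_acc, c(0.25, 0.5, 0.75),
                                         names = FALSE),
      fold_test_accuracy = test_acc,
      fold_generalisation_accuracy = gen_acc,
      coefficients = coefs,
      significant_1pct = sig,
      significant_all_folds =
        colnames(sig)[colSums(sig, na.rm = TRUE) == n_folds &
                        colSums(!is.na(sig)) == n_folds],
      separation_flagged = any_sep),
      class = "transfer_report")
  })
}

#' @export
print.transfer_report <- function(x, ...) {
  q <- function(v) sprintf("median %.3f (Q1 %.3f, Q3 %.3f)", v[2], v[1],
                           v[3])
  cat(sprintf("state-value transfer report (%s features, %d folds)\n",
              x$feature_subset, x$n_folds))
  cat("  test accuracy:          ", q(x$test_accuracy), "\n")
  cat("  generalisation accuracy:", q(x$generalisation_accuracy), "\n")
  if (length(x$significant_all_folds))
    cat("  coefficients significant (1%) in all folds:",
        paste(x$significant_all_folds, collapse = ", "), "\n")
  if (x$separation_flagged)
    cat("  note: ridge fallback used in at least one fold\n")
  invisible(x)
}

#' Write a transfer report to JSON
#'
#' @param report A [evaluate_transfer()] result.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_transfer_report <- function(report, path) {
  obj <- list(
    feature_subset = report$feature_subset,
    n_folds = report$n_folds,
    test_accuracy = list(q1 = report$test_accuracy[1],
                         median = report$test_accuracy[2],
                         q3 = report$test_accuracy[3]),
    generalisation_accuracy = list(
      q1 = report$generalisation_accuracy[1],
      median = report$generalisation_accuracy[2],
      q3 = report$generalisation_accuracy[3]),
    significant_all_folds = report$significant_all_folds,
    separation_flagged = report$separation_flagged)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
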