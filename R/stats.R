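#' Participant-level bootstrap test for a difference
#'
#' Percentile bootstrap at the participant level. In paired mode the
#' aligned per-participant pairs are resampled with replacement and the
#' statistic of the difference distribution recomputed per resample; in
#' unpaired mode the two samples are resampled independently. The
#' two-sided p-value is `2 * min(P(diff* <= 0), P(diff* >= 0))` over the
#' bootstrap distribution of the difference `statistic(b) - statistic(a)`.
#'
#' @param a,b Per-participant values (equal-length and aligned when
#'   `paired = TRUE`).
#' @param statistic `"mean"` or `"median"`.
#' @param paired Resample aligned pairs (default TRUE).
#' @param n_resamples Number of bootstrap resamples (default 10000).
#' @param seed Integer seed (optional).
#' @return Object of class `bootstrap_result` with fields `statistic`,
#'   `observed` (difference b - a), `boot_median`, `ci` (2.5/97.5
#'   percentiles), `p_value`, `n_resamples`, `seed`.
#' @export
bootstrap_diff_test <- function(a, b, statistic = c("mean", "median"),
                                paired = TRUE, n_resamples = 10000L,
                                seed = NULL) {
  statistic <- match.arg(statistic)
  if (paired) {
    keep <- !is.na(a) & !is.na(b)
    a <- a[keep]; b <- b[keep]
    if (length(a) != length(b)) stopf("paired mode needs aligned vectors")
  } else {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
  }
  if (length(a) < 3L || length(b) < 3L)
    stopf("at least 3 participants are required per sample")
  stat_fun <- if (statistic == "mean") mean else median
  with_seed(seed, {
    if (paired) {
      d <- b - a
      n <- length(d)
      idx <- matrix(sample.int(n, n * n_resamples, replace = TRUE),
                    n_resamples, n)
      dm <- matrix(d[idx], n_resamples, n)
      boot <- if (statistic == "mean") rowMeans(dm) else
        apply(dm, 1L, median)
      observed <- stat_fun(d)
    } else {
      na <- length(a); nb <- length(b)
      ia <- matrix(sample.int(na, na * n_resamples, replace = TRUE),
                   n_resamples, na)
      ib <- matrix(sample.int(nb, nb * n_resamples, replace = TRUE),
                   n_resamples, nb)
      am <- matrix(a[ia], n_resamples, na)
      bm <- matrix(b[ib], n_resamples, nb)
      boot <- if (statistic == "mean") rowMeans(bm) - rowMeans(am) else
        apply(bm, 1L, median) - apply(am, 1L, median)
      observed <- stat_fun(b) - stat_fun(a)
    }
    # small-sample variance correction: the bootstrap distribution of a
    # mean is narrower than the sampling distribution by (n - 1) / n, so
    # rescale the resampled statistics about the observed value
    n_eff <- if (paired) length(a) else 2 / (1 / length(a) + 1 / length(b))
    boot <- observed + (boot - observed) * sqrt(n_eff / (n_eff - 1))
    # finite-resample correction: count the observed sample as one resample
    p <- 2 * min((sum(boot <= 0) + 1) / (n_resamples + 1),
                 (sum(boot >= 0) + 1) / (n_resamples + 1))
    structure(list(statistic = statistic, observed = observed,
                   boot_median = median(boot),
                   ci = quantile(boot, c(0.025, 0.975), names = FALSE),
                   p_value = min(p, 1), n_resamples = n_resamples,
                   paired = paired, seed = seed),
              class = "bootstrap_result")
  })
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "%s bootstrap test (%s): diff = %.4f [%.4f, %.4f], p = %.4g (%d resamples)\n",
    if (x$paired) "paired" else "unpaired", x$statistic, x$observed,
    x$ci[1], x$ci[2], x$p_value, x$n_resamples))
  invisible(x)
}

# Logistic slope of success on cumulative trial number for one
# participant-condition cell, with a ridge fallback for degenerate cells.
.success_slope <- function(success, trial_number) {
  x <- trial_number - mean(trial_number)
  if (all(success) || !any(success)) {
    b <- .ridge_logistic(cbind(1, x), as.integer(success), lambda = 0.1)
    return(structure(b[2], flagged = TRUE))
  }
  fit <- suppressWarnings(glm.fit(cbind(1, x), as.integer(success),
                                  family = binomial()))
  if (!fit$converged || any(abs(fit$coefficients) > 1e3)) {
    b <- .ridge_logistic(cbind(1, x), as.integer(success), lambda = 0.1)
    return(structure(b[2], flagged = TRUE))
  }
  structure(unname(fit$coefficients[2]), flagged = FALSE)
}

#' Learning-rate contrast between probe and training conditions
#'
#' A two-stage surrogate for a hierarchical trial-level model: per
#' participant and condition, the logistic slope of trial success on
#' cumulative trial number is fitted; the probe-minus-training slope
#' difference is then summarised with a participant-level bootstrap
#' percentile interval. Degenerate all-success/all-failure cells use a
#' ridge-penalised slope and are flagged.
#'
#' @param trials Data frame with columns `participant`, `condition`
#'   (`"training"` or `"probe"`), `trial` (cumulative trial number within
#'   condition), `success` (logical or 0/1).
#' @param n_resamples Bootstrap resamples for the interval.
#' @param seed Integer seed (optional).
#' @return Object of class `contrast_result` with per-condition mean
#'   slopes, the mean difference, its bootstrap interval, and
#'   `direction` (`TRUE` when the interval excludes 0).
#' @export
learning_rate_contrast <- function(trials, n_resamples = 5000L,
                                   seed = NULL) {
  stopifnot(all(c("participant", "condition", "trial", "success") %in%
                  names(trials)))
  parts <- unique(trials$participant)
  if (length(parts) < 2L)
    stopf("at least 2 participants are required for the contrast")
  slope_tab <- do.call(rbind, lapply(parts, function(p) {
    row <- list(participant = p)
    for (cond in c("training", "probe")) {
      sel <- trials$participant == p & trials$condition == cond
      if (sum(sel) < 2L)
        stopf("participant %s has fewer than 2 %s trials", p, cond)
      sl <- .success_slope(as.logical(trials$success[sel]),
                           trials$trial[sel])
      row[[cond]] <- as.numeric(sl)
      row[[paste0(cond, "_flagged")]] <- attr(sl, "flagged")
    }
    as.data.frame(row)
  }))
  d <- slope_tab$probe - slope_tab$training
  with_seed(seed, {
    n <- length(d)
    idx <- matrix(sample.int(n, n * n_resamples, replace = TRUE),
                  n_resamples, n)
    boot <- rowMeans(matrix(d[idx], n_resamples, n))
    ci <- quantile(boot, c(0.025, 0.975), names = FALSE)
    structure(list(slopes = slope_tab,
                   training_slope = mean(slope_tab$training),
                   probe_slope = mean(slope_tab$probe),
                   difference = mean(d), ci = ci,
                   direction = ci[1] > 0 || ci[2] < 0,
                   any_flagged = any(slope_tab$training_flagged |
                                       slope_tab$probe_flagged),
                   n_resamples = n_resamples, seed = seed),
              class = "contrast_result")
  })
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf(
    paste0("learning-rate contrast (logit/trial): training %.4f, probe",
           " %.4f\n  probe - training = %.4f [%.4f, %.4f]%s\n"),
    x$training_slope, x$probe_slope, x$difference, x$ci[1], x$ci[2],
    if (x$direction) " (interval excludes 0)" else ""))
  invisible(x)
}

#' Assemble the block-level analysis table
#'
#' Joins per-block performance measures, strategy weights, and per-session
#' working-memory scores into one model-ready row per participant and
#' block, with the block coding used for regression analyses (training
#' blocks 2-7; probe blocks 0 and 1) and block-by-strategy interaction
#' columns.
#'
#' @param measures Output of [block_measures()].
#' @param strategy Data frame with `participant`, `block`, `x`, `y`, `z`
#'   pairwise strategy preferences.
#' @param wm_scores Data frame with `participant`, `session`, `wm_score`.
#' @return Data frame, one row per participant and block; rows without a
#'   strategy report are flagged via `has_strategy`.
#' @export
build_block_table <- function(measures, strategy, wm_scores) {
  code <- c(p1 = 0L, t1 = 2L, t2 = 3L, t3 = 4L, t4 = 5L, t5 = 6L,
            t6 = 7L, p2 = 1L)
  out <- measures
  out$block_code <- code[out$block]
  out$is_probe <- out$block %in% c("p1", "p2")
  if (!is.null(strategy)) {
    w <- strategy_weights(strategy$x, strategy$y, strategy$z)
    strategy <- cbind(strategy[, c("participant", "block")], w)
    out <- merge(out, strategy, by = c("participant", "block"),
                 all.x = TRUE)
  } else {
    out$w_t <- out$w_w <- out$w_i <- NA_real_
  }
  out$has_strategy <- !is.na(out$w_t)
  out <- merge(out, wm_scores, by = c("participant", "session"),
               all.x = TRUE)
  out$block_x_wt <- out$block_code * out$w_t
  out$block_x_ww <- out$block_code * out$w_w
  out$block_x_wi <- out$block_code * out$w_i
  out[order(out$participant, out$session, out$block_code), ]
}

#' Per-participant, per-session working-memory scores for a cohort
#'
#' @param wm List of working-memory outcome records (as produced by
#'   [simulate_cohort()] or read from disk).
#' @return Data frame `participant`, `session`, `wm_score`, `flag`.
#' @export
wm_score_table <- function(wm) {
  pid <- vapply(wm, function(w) as.character(w$participant), character(1))
  sess <- vapply(wm, function(w) as.integer(w$session), integer(1))
  rows <- list()
  for (p in unique(pid)) {
    for (s in sort(unique(sess[pid == p]))) {
      sc <- wm_score(wm[pid == p & sess == s])
      rows[[length(rows) + 1L]] <- data.frame(
        participant = p, session = s, wm_score = as.numeric(sc),
        flag = attr(sc, "flag"), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Probe-versus-training transfer analysis of a cohort
#'
#' The headline contrast of the experimental design: the change in per-participant
#' solved proportion across the probe blocks (p2 - p1) is compared with the
#' change across the first two training blocks (t2 - t1) by a paired
#' participant-level bootstrap test. A cohort whose probe improvement
#' exceeds what direct practice produced in the equivalent training blocks
#' is flagged as showing transfer.
#'
#' @param trials List of [trial_record()] objects for the cohort.
#' @param n_resamples Bootstrap resamples.
#' @param seed Integer seed (optional).
#' @param alpha Significance level for the transfer flag.
#' @return List with the per-block solved-proportion table, the bootstrap
#'   test, and `transfer_flag` (significant AND probe change larger).
#' @export
transfer_analysis <- function(trials, n_resamples = 10000L, seed = NULL,
                              alpha = 0.05) {
  bm <- block_measures(trials)
  wide <- function(blk) {
    v <- bm$prop_solved[bm$block == blk]
    names(v) <- bm$participant[bm$block == blk]
    v
  }
  p1 <- wide("p1"); p2 <- wide("p2"); t1 <- wide("t1"); t2 <- wide("t2")
  common <- Reduce(intersect, list(names(p1), names(p2), names(t1),
                                   names(t2)))
  probe_change <- p2[common] - p1[common]
  train_change <- t2[common] - t1[common]
  test <- bootstrap_diff_test(train_change, probe_change,
                              statistic = "mean", paired = TRUE,
                              n_resamples = n_resamples, seed = seed)
  list(block_table = bm, probe_change = probe_change,
       train_change = train_change, test = test,
       transfer_flag = test$p_value < alpha && test$observed > 0)
}
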