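#' Event-window specification for response analysis
#'
#' @param pre_s,post_s pre- and post-event heart-rate windows, s (defaults 5
#'   and 10).
#' @param rt_bin reaction-time bin width, s (default 0.1); bins are
#'   left-closed, right-open, anchored at 0.
#' @param max_rt maximum allowed reaction time, s.
#' @return object of class `event_window_spec`.
#' @export
event_window_spec <- function(pre_s = 5, post_s = 10, rt_bin = 0.1,
                              max_rt = 1) {
  stopifnot(pre_s > 0, post_s > 0, rt_bin > 0, max_rt > 0)
  structure(list(pre_s = pre_s, post_s = post_s, rt_bin = rt_bin,
                 max_rt = max_rt), class = "event_window_spec")
}

#' Score a clock-task log
#'
#' Events are the correct (C), wrong (W) and missed (M) outcomes; silent
#' normal steps are not events. The probability of correct response is
#' `PoCR = C / (C + W + M)`, undefined (`NA` with a flag) when the log holds
#' no events.
#'
#' @param log a `task_event_log` (see [generate_task_log()]).
#' @return list with `counts` (named C/W/M), `pocr` and `defined`.
#' @export
score_events <- function(log) {
  counts <- c(C = sum(log$outcome == "correct"),
              W = sum(log$outcome == "wrong"),
              M = sum(log$outcome == "missed"))
  total <- sum(counts)
  list(counts = counts,
       pocr = if (total > 0) unname(counts["C"] / total) else NA_real_,
       defined = total > 0)
}

# mean HR (beats/min) from the IBI samples timestamped inside [t0, t1)/(t0,t1]
mean_hr_window <- function(beats, lo, hi, closed_right = FALSE) {
  sel <- if (closed_right) beats$time > lo & beats$time <= hi
         else beats$time >= lo & beats$time < hi
  ibi <- beats$ibi[sel]
  if (!length(ibi)) return(NA_real_)
  60 / mean(ibi)
}

#' Event-locked heart-rate ratios by reaction-time bin
#'
#' For every task event (stimulus-locked at the jump step time), computes
#' `HRpost / HRpre` from the mean IBI in the `[t - pre, t)` and `(t, t + post]`
#' windows, assigns the event to its 100 ms reaction-time bin, and returns the
#' per-bin mean ratio, PoCR and event count. Missed jumps carry the fixed
#' maximum RT (they enter the last bin) but are excluded from mean-RT
#' statistics elsewhere. Events whose windows lack clean IBI are dropped and
#' counted.
#'
#' @param beats a `beat_series` covering the task.
#' @param log a `task_event_log`.
#' @param spec an [event_window_spec()].
#' @param include_missed include missed jumps at `rt = max_rt`.
#' @return data frame with columns `rt_bin_lo`, `rt_bin_hi`, `pocr`,
#'   `mean_ratio`, `n`; attribute `n_dropped` counts events without usable
#'   beat coverage.
#' @export
hr_ratio_by_event <- function(beats, log, spec = event_window_spec(),
                              include_missed = TRUE) {
  ev <- log[log$outcome != "none", , drop = FALSE]
  if (!include_missed) ev <- ev[ev$outcome != "missed", , drop = FALSE]
  rt <- ifelse(ev$outcome == "missed", spec$max_rt, ev$rt)
  ratio <- rep(NA_real_, nrow(ev))
  for (i in seq_len(nrow(ev))) {
    t <- ev$step_time[i]
    pre <- mean_hr_window(beats, t - spec$pre_s, t)
    post <- mean_hr_window(beats, t, t + spec$post_s, closed_right = TRUE)
    if (!is.na(pre) && !is.na(post) && pre > 0) ratio[i] <- post / pre
  }
  ok <- !is.na(ratio) & !is.na(rt)
  bin <- floor(rt[ok] / spec$rt_bin)
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    data.frame(rt_bin_lo = b * spec$rt_bin, rt_bin_hi = (b + 1) * spec$rt_bin,
               pocr = mean(ev$outcome[ok][sel] == "correct"),
               mean_ratio = mean(ratio[ok][sel]), n = sum(sel))
  }))
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Session-level heart-rate ratio and mean reaction time
#'
#' Ratio of the mean heart rate in the attention routine to the relaxed
#' routine, and the mean reaction time over responded events only (missed
#' jumps, which carry the fixed maximum RT, are excluded).
#'
#' @param beats_R,beats_A `beat_series` for the two routines.
#' @param log_A the attention-routine `task_event_log`.
#' @return list with `hr_ratio`, `mean_rt` (`NA` with `mean_rt_defined =
#'   FALSE` when no responded events exist).
#' @export
session_hr_ratio <- function(beats_R, beats_A, log_A) {
  stopifnot(nrow(beats_R) > 0, nrow(beats_A) > 0)
  hr_R <- 60 / mean(beats_R$ibi, na.rm = TRUE)
  hr_A <- 60 / mean(beats_A$ibi, na.rm = TRUE)
  rts <- log_A$rt[log_A$responded]
  list(hr_ratio = hr_A / hr_R,
       mean_rt = if (length(rts)) mean(rts, na.rm = TRUE) else NA_real_,
       mean_rt_defined = length(rts) > 0)
}

#' Attention-level timeline
#'
#' Per time bin (default 30 s, left-closed), the attention level
#' `(C - W - M) / (C + W + M)`; bins without events are flagged undefined.
#'
#' @param log a `task_event_log`.
#' @param bin_s bin width, s.
#' @return data frame with `bin_start`, `level`, `n`, `defined`.
#' @export
attention_timeline <- function(log, bin_s = 30) {
  ev <- log[log$outcome != "none", , drop = FALSE]
  edges <- seq(0, max(log$step_time), by = bin_s)
  do.call(rbind, lapply(edges, function(b) {
    sel <- ev$step_time >= b & ev$step_time < b + bin_s
    C <- sum(ev$outcome[sel] == "correct")
    W <- sum(ev$outcome[sel] == "wrong")
    M <- sum(ev$outcome[sel] == "missed")
    n <- C + W + M
    data.frame(bin_start = b,
               level = if (n > 0) (C - W - M) / n else NA_real_,
               n = n, defined = n > 0)
  }))
}

#' Bland--Altman agreement between two paired series
#'
#' Pairs samples by nearest event time within a tolerance, then computes
#' Pearson's r, the mean difference (bias) `m = mean(x - y)` and the limits of
#' agreement `m +/- 1.96 * sd(x - y)`, within which 95% of the differences
#' are expected.
#'
#' @param x,y either numeric vectors of equal length (already paired) or
#'   two-column data frames `(time, value)` to be matched on time.
#' @param tol pairing tolerance, s (nearest neighbour on event times).
#' @return object of class `agreement_stats`: `pearson_r`, `m`, `loa_low`,
#'   `loa_high`, `n`.
#' @export
agreement <- function(x, y, tol = 0.5) {
  if (is.data.frame(x) && is.data.frame(y)) {
    xi <- x[[2]]; yi <- rep(NA_real_, nrow(x))
    for (i in seq_len(nrow(x))) {
      j <- which.min(abs(y[[1]] - x[[1]][i]))
      if (abs(y[[1]][j] - x[[1]][i]) <= tol) yi[i] <- y[[2]][j]
    }
    keep <- !is.na(yi)
    xv <- xi[keep]; yv <- yi[keep]
  } else {
    stopifnot(length(x) == length(y))
    xv <- x; yv <- y
  }
  if (length(xv) < 3) stop("fewer than 3 matched pairs")
  d <- xv - yv
  m <- mean(d); s <- sd(d)
  r <- if (sd(xv) > 0 && sd(yv) > 0) cor(xv, yv) else 1
  structure(list(pearson_r = r, m = m, loa_low = m - 1.96 * s,
                 loa_high = m + 1.96 * s, n = length(xv)),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf(
    "agreement: r = %.3f, bias m = %.4f, LoA [%.4f, %.4f], n = %d\n",
    x$pearson_r, x$m, x$loa_low, x$loa_high, x$n))
  invisible(x)
}
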