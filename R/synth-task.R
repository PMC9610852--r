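#' Responder model for the clock vigilance task
#'
#' Behavioural parameters of the simulated participant: lognormal reaction
#' times (truncated at the allowed maximum), a miss probability on jump steps
#' and a false-press probability on normal steps.
#'
#' @param rt_median median reaction time, s.
#' @param rt_sdlog lognormal shape (sd of log RT).
#' @param miss_prob probability of not responding to a jump.
#' @param false_press_prob probability of pressing on a normal step.
#' @return object of class `responder_model`.
#' @export
responder_model <- function(rt_median = 0.45, rt_sdlog = 0.25,
                            miss_prob = 0.08, false_press_prob = 0.01) {
  stop_if_not_scalar(rt_median, "rt_median", 0)
  stop_if_not_scalar(rt_sdlog, "rt_sdlog", 0)
  stop_if_not_scalar(miss_prob, "miss_prob", 0, 1)
  stop_if_not_scalar(false_press_prob, "false_press_prob", 0, 1)
  structure(list(rt_median = rt_median, rt_sdlog = rt_sdlog,
                 miss_prob = miss_prob, false_press_prob = false_press_prob),
            class = "responder_model")
}

#' Simulate a clock-task event log
#'
#' The clock hand advances one fixed step per second (3.6 degrees at 3.6
#' degrees/s); each step is independently a larger "jump" (5.4 degrees) with
#' probability `jump_prob` (default 0.1). The responder answers jumps within
#' the allowed maximum reaction time unless it misses, and occasionally
#' false-presses on a normal step. Outcomes: press on a jump within `max_rt`
#' is `correct`; press on a normal step is `wrong`; an unanswered jump is
#' `missed`; silent normal steps carry no outcome.
#'
#' @param duration task length, s (>= 1).
#' @param step_rate clock-hand step rate, deg/s (one step per second).
#' @param jump_prob per-step probability of the larger jump; must be in
#'   `[0, 1]`.
#' @param max_rt maximum allowed reaction time, s.
#' @param responder a [responder_model()].
#' @param seed integer seed.
#' @return Data frame of class `task_event_log` with columns `step_time` (s),
#'   `is_jump`, `responded`, `rt` (s, `NA` when not responded) and `outcome`
#'   (`correct`/`wrong`/`missed`/`none`).
#' @export
generate_task_log <- function(duration, step_rate = 3.6, jump_prob = 0.1,
                              max_rt = 1, responder = responder_model(),
                              seed = 1L) {
  if (duration < 1) stop("duration must be >= 1 s")
  stop_if_not_scalar(jump_prob, "jump_prob", 0, 1)
  stopifnot(inherits(responder, "responder_model"))
  with_seed(seed, {
    step_time <- seq_len(floor(duration))
    n <- length(step_time)
    is_jump <- runif(n) < jump_prob
    miss <- runif(n) < responder$miss_prob
    false_press <- runif(n) < responder$false_press_prob
    rt_draw <- rlnorm(n, meanlog = log(responder$rt_median),
                      sdlog = responder$rt_sdlog)
    rt_draw <- pmin(rt_draw, max_rt)        # truncated at the allowed maximum
    responded <- (is_jump & !miss) | (!is_jump & false_press)
    rt <- ifelse(responded, rt_draw, NA_real_)
    outcome <- rep("none", n)
    outcome[is_jump & responded] <- "correct"
    outcome[is_jump & !responded] <- "missed"
    outcome[!is_jump & responded] <- "wrong"
    out <- data.frame(step_time = step_time, is_jump = is_jump,
                      responded = responded, rt = rt, outcome = outcome)
    attr(out, "max_rt") <- max_rt
    attr(out, "step_rate") <- step_rate
    class(out) <- c("task_event_log", "data.frame")
    out
  })
}
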