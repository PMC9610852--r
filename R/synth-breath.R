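#' Generate ground-truth breath timing for a synthetic session
#'
#' Draws a sequence of breaths covering `[0, duration]`. Each breath k is
#' described by its inspire-begin time `tb[k]`, inspire-end time `te[k]`, and
#' amplitude `iv[k]`; consecutive inspire-ends are separated by the
#' inter-respiration interval `iri[k] = te[k] - te[k-1]`, split into the
#' inspiratory interval `ii[k] = te[k] - tb[k]` and expiratory interval
#' `ei[k] = tb[k] - te[k-1]`. Intervals are drawn around `60 / mean_rr` with a
#' standard deviation mapped from the rate variability `rr_sd` (delta method),
#' truncated at 3 sigma and clipped to the physiological band of 6--40
#' breaths/min. With probability `pause_prob` a breath's expiration ends in a
#' flat pause of `pause_dur` seconds immediately before the next inspiration.
#'
#' @param params a [resp_params()] object.
#' @param duration session length, s; must exceed three mean breath periods.
#' @param seed integer seed.
#' @return A data frame of class `breath_truth` with columns `tb`, `te`, `iri`,
#'   `ii`, `ei`, `iv`, `pause`, `pause_dur` (one row per breath; `iri`/`ei` of
#'   the first breath are `NA` since it has no predecessor). The session
#'   `duration` and `params` are attached as attributes.
#' @export
generate_breath_truth <- function(params, duration, seed = 1L) {
  if (!inherits(params, "resp_params"))
    params <- do.call(resp_params, params)   # validates ranges, incl. mean_rr
  mean_iri <- 60 / params$mean_rr
  if (duration <= 3 * mean_iri)
    stop("duration must exceed 3 breath periods (", round(3 * mean_iri, 1),
         " s)")
  with_seed(seed, {
    n_max <- ceiling(duration / (60 / 40)) + 2L
    z_iri <- rnorm_trunc3(n_max)
    z_ii <- rnorm_trunc3(n_max)
    z_iv <- rnorm_trunc3(n_max)
    pause_draw <- runif(n_max) < params$pause_prob

    sd_iri <- 60 * params$rr_sd / params$mean_rr^2      # delta method
    rel_sd <- params$rr_sd / params$mean_rr
    iri <- pmin(pmax(mean_iri + sd_iri * z_iri, 60 / 40 + 0.05), 60 / 6 - 0.05)
    ii <- params$ii_fraction * iri * (1 + 0.5 * rel_sd * z_ii)
    ii <- pmin(pmax(ii, 0.2 * iri), 0.8 * iri)
    iv <- pmax(1 + params$iv_cv * z_iv, 0.2)

    # first breath: place its inspire-end one mean period in
    te1 <- min(mean_iri, duration / 4)
    tb1 <- te1 - ii[1]
    if (tb1 < 0) { tb1 <- 0.05; ii[1] <- te1 - tb1 }
    te <- te1; tb <- tb1
    k <- 1L
    # keep the last inspire-end clear of the record tail so that detection
    # with a ~0.7-period MAC window (and its edge guard) can see every breath
    tail_margin <- 0.75 * mean_iri + 0.5
    while (te[k] + iri[k + 1] <= duration - tail_margin && k + 1L <= n_max) {
      k <- k + 1L
      te[k] <- te[k - 1] + iri[k]
      tb[k] <- te[k] - ii[k]
    }
    n <- k
    ei <- c(NA_real_, tb[2:n] - te[1:(n - 1)])
    # pause requires room for the expiratory fall before it
    pause <- pause_draw[1:n] & !is.na(ei) & (ei - params$pause_dur >= 0.4)
    out <- data.frame(
      tb = tb, te = te[1:n],
      iri = c(NA_real_, diff(te[1:n])),
      ii = ii[1:n], ei = ei, iv = iv[1:n],
      pause = pause,
      pause_dur = ifelse(pause, params$pause_dur, 0))
    attr(out, "duration") <- duration
    attr(out, "params") <- params
    class(out) <- c("breath_truth", "data.frame")
    out
  })
}

#' Construct a breath-truth table from explicit timings
#'
#' Low-level constructor used to build hand-specified breath sequences (e.g.
#' fixtures exercising pause handling). Derived intervals are computed from the
#' given `tb`/`te` and validated against the breath-timing invariants.
#'
#' @param tb,te inspire-begin and inspire-end times, s (equal length,
#'   interleaved `tb[k] < te[k] < tb[k+1]`).
#' @param iv inspiratory amplitudes (recycled).
#' @param pause logical, whether the expiration *preceding* each breath ends in
#'   a flat pause; `pause_dur` its duration in s (recycled).
#' @param duration session length, s; defaults to just past the last breath.
#' @return a `breath_truth` data frame, as from [generate_breath_truth()].
#' @export
breath_truth <- function(tb, te, iv = 1, pause = FALSE, pause_dur = 0,
                         duration = max(te) + 2) {
  stopifnot(length(tb) == length(te), all(te > tb))
  n <- length(te)
  if (n > 1 && any(tb[-1] <= te[-n])) stop("need te[k-1] < tb[k] < te[k]")
  out <- data.frame(
    tb = tb, te = te,
    iri = c(NA_real_, diff(te)),
    ii = te - tb,
    ei = c(NA_real_, tb[-1] - te[-n]),
    iv = rep_len(iv, n),
    pause = rep_len(pause, n),
    pause_dur = rep_len(pause_dur, n) * rep_len(pause, n))
  attr(out, "duration") <- duration
  class(out) <- c("breath_truth", "data.frame")
  out
}

#' Render a respiration waveform from breath truth
#'
#' Builds a piecewise-smooth displacement trace: each inspiration rises from
#' `r(tb)` to `r(te) = r(tb) + iv` as a raised cosine over `ii` seconds; each
#' expiration falls back as a raised cosine over the non-pause portion of `ei`
#' and then stays flat through any end-expiratory pause until the next
#' inspire-begin. Every ground-truth `te` is thus a local maximum of the trace
#' (within one sample) and `r(te) - r(tb)` equals the truth amplitude exactly.
#'
#' @param truth a [generate_breath_truth()] result.
#' @param fs sampling rate, Hz (>= 10).
#' @return object of class `waveform`: `list(samples, fs, t0)`.
#' @export
render_respiration <- function(truth, fs = 100) {
  stopifnot(inherits(truth, "breath_truth"))
  if (fs < 10) stop("fs < 10 Hz undersamples the respiration waveform")
  duration <- attr(truth, "duration")
  n <- floor(duration * fs) + 1L
  t <- (seq_len(n) - 1L) / fs
  x <- numeric(n)
  nb <- nrow(truth)
  rise <- function(tt, t0, dur, a) a * 0.5 * (1 - cos(pi * (tt - t0) / dur))
  for (k in seq_len(nb)) {
    # inspiration tb -> te
    sel <- t >= truth$tb[k] & t <= truth$te[k]
    x[sel] <- rise(t[sel], truth$tb[k], truth$ii[k], truth$iv[k])
    # expiration te -> next tb (fall then optional flat pause)
    end_exp <- if (k < nb) truth$tb[k + 1] else min(duration,
                                                    truth$te[k] + 2.5)
    p <- if (k < nb) truth$pause_dur[k + 1] else 0
    fall_dur <- max(end_exp - truth$te[k] - p, 1 / fs)
    sel <- t > truth$te[k] & t <= end_exp
    tt <- t[sel]
    x[sel] <- ifelse(tt <= truth$te[k] + fall_dur,
                     truth$iv[k] * 0.5 *
                       (1 + cos(pi * (tt - truth$te[k]) / fall_dur)),
                     0)
  }
  structure(list(samples = x, fs = fs, t0 = 0), class = "waveform")
}

#' Instantaneous breath phase from breath truth
#'
#' Returns a function of time giving the breath-cycle phase in radians, rising
#' linearly from 0 to 2*pi between consecutive inspire-end points. Used as the
#' respiration-coupling input of [generate_beat_truth()] (RSA).
#'
#' @param truth a [generate_breath_truth()] result.
#' @return `function(t)` returning phase in `[0, 2*pi)`.
#' @export
breath_phase <- function(truth) {
  stopifnot(inherits(truth, "breath_truth"))
  te <- truth$te
  cum <- 2 * pi * (seq_along(te) - 1)
  f <- approxfun(te, cum, rule = 2)
  function(t) {
    ph <- f(t)
    # extrapolate with the edge breathing rate so coupling never freezes
    lo <- t < te[1]; hi <- t > te[length(te)]
    if (any(lo)) ph[lo] <- cum[1] - 2 * pi * (te[1] - t[lo]) / diff(te[1:2])
    if (any(hi)) {
      last_iri <- te[length(te)] - te[length(te) - 1]
      ph[hi] <- cum[length(cum)] + 2 * pi * (t[hi] - te[length(te)]) / last_iri
    }
    ph %% (2 * pi)
  }
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("waveform: %d samples @ %g Hz (%.1f s)%s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              if (!is.null(x$kind)) paste0(", kind=", x$kind) else ""))
  invisible(x)
}
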