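#' Generate ground-truth heartbeat timing
#'
#' Draws beat times over `[0, duration]` with inter-beat intervals
#' `ibi = (60/mean_hr) * (1 + lf_amp*sin(2*pi*lf_freq*t) + hf_amp*c(t) + e)`,
#' where `c(t) = sin(breath phase)` is the respiration coupling (respiratory
#' sinus arrhythmia) and `e` is truncated white noise with relative standard
#' deviation `hr_sd / mean_hr`. Modulation depths that could drive an interval
#' to zero are rejected.
#'
#' @param params a [cardiac_params()] object.
#' @param resp_phase respiration phase: a function of time returning radians
#'   (see [breath_phase()]), or `NULL` for no coupling.
#' @param duration session length, s.
#' @param seed integer seed.
#' @return Data frame of class `beat_truth` with columns `time` (beat times, s)
#'   and `ibi` (interval following each beat; last is `NA`).
#' @export
generate_beat_truth <- function(params, resp_phase = NULL, duration,
                                seed = 1L) {
  if (!inherits(params, "cardiac_params"))
    params <- do.call(cardiac_params, params)
  rel_sd <- params$hr_sd / params$mean_hr
  depth <- params$lf_amp + params$hf_amp + 3 * rel_sd
  if (depth >= 1)
    stop("modulation depths (", round(depth, 2),
         ") would allow non-positive IBI")
  coupling <- if (is.null(resp_phase)) function(t) 0
              else function(t) sin(resp_phase(t))
  b0 <- 60 / params$mean_hr
  with_seed(seed, {
    n_max <- ceiling(duration / (60 / 115)) + 2L
    z <- rnorm_trunc3(n_max)
    times <- numeric(n_max)
    ibi <- numeric(n_max)
    t <- 0.3                     # first beat shortly after session start
    k <- 0L
    while (t <= duration) {
      k <- k + 1L
      times[k] <- t
      ibi[k] <- b0 * (1 + params$lf_amp * sin(2 * pi * params$lf_freq * t) +
                        params$hf_amp * coupling(t) + rel_sd * z[k])
      t <- t + ibi[k]
    }
    out <- data.frame(time = times[1:k], ibi = c(ibi[1:(k - 1)], NA_real_))
    attr(out, "duration") <- duration
    attr(out, "params") <- params
    class(out) <- c("beat_truth", "data.frame")
    out
  })
}

# Instantaneous heartbeat phase (radians) from truth beat times: 2*pi per beat,
# linearly interpolated, constant-rate extrapolation at the edges.
heartbeat_phase <- function(beat_truth) {
  bt <- beat_truth$time
  stopifnot(length(bt) >= 2)
  cum <- 2 * pi * (seq_along(bt) - 1)
  f <- approxfun(bt, cum, rule = 2)
  first_ibi <- bt[2] - bt[1]
  last_ibi <- bt[length(bt)] - bt[length(bt) - 1]
  function(t) {
    ph <- f(t)
    lo <- t < bt[1]; hi <- t > bt[length(bt)]
    if (any(lo)) ph[lo] <- -2 * pi * (bt[1] - t[lo]) / first_ibi
    if (any(hi)) ph[hi] <- cum[length(cum)] +
        2 * pi * (t[hi] - bt[length(bt)]) / last_ibi
    ph
  }
}

# Render the mechanical heartbeat trace (fundamental + second harmonic) on a
# uniform grid. The second harmonic's relative amplitude comes from params.
render_heartbeat <- function(beat_truth, fs, duration,
                             harmonic2_rel_amp = NULL) {
  h2 <- harmonic2_rel_amp %||% attr(beat_truth, "params")$harmonic2_rel_amp
  h2 <- h2 %||% 0.5
  ph <- heartbeat_phase(beat_truth)
  t <- seq(0, duration, by = 1 / fs)
  phi <- ph(t)
  structure(list(samples = sin(phi) + h2 * sin(2 * phi), fs = fs, t0 = 0),
            class = "waveform")
}
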