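#' Construct a raw four-channel session container
#'
#' The canonical container for one session's baseband recording: the four
#' channels (`thorax_amp`, `thorax_phase`, `abd_amp`, `abd_phase`) as equal
#' length finite numeric vectors, the sampling rate and start time, plus any
#' attached ground truth.
#'
#' @param channels named list of the 4 channel vectors.
#' @param fs sampling rate, Hz (> 0).
#' @param t0 session start time, s.
#' @param truth optional list of ground-truth tables (e.g. `breaths`, `beats`).
#' @return object of class `raw_channel_set`.
#' @export
raw_channel_set <- function(channels, fs, t0 = 0, truth = NULL) {
  nm <- c("thorax_amp", "thorax_phase", "abd_amp", "abd_phase")
  if (!setequal(names(channels), nm))
    stop("channels must be exactly: ", paste(nm, collapse = ", "))
  channels <- channels[nm]
  len <- unique(vapply(channels, length, 1L))
  if (length(len) != 1) stop("channel lengths differ")
  if (!all(vapply(channels, function(x) all(is.finite(x)), TRUE)))
    stop("channels must be finite")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be > 0")
  structure(list(channels = channels, fs = fs, t0 = t0, truth = truth),
            class = "raw_channel_set")
}

#' @export
print.raw_channel_set <- function(x, ...) {
  cat(sprintf("raw_channel_set: 4 channels x %d samples @ %g Hz (%.1f s)%s\n",
              length(x$channels[[1]]), x$fs,
              length(x$channels[[1]]) / x$fs,
              if (!is.null(x$truth)) ", with ground truth" else ""))
  invisible(x)
}

#' Mix respiration and heartbeat into four noisy baseband channels
#'
#' Each channel is `resp_gain * respiration + heart_gain * heartbeat + drift +
#' white noise`, where the heartbeat trace contains the fundamental plus its
#' (relative-amplitude) second harmonic, and drift is a slow (< 0.05 Hz)
#' sinusoid with a per-channel random phase. Ground truth is attached to the
#' returned container so recovery tests need no joins.
#'
#' @param resp_wave respiration [`waveform`][render_respiration] on the target
#'   grid.
#' @param beat_truth a [generate_beat_truth()] result.
#' @param mix a [channel_mix()].
#' @param fs sampling rate, Hz; must match `resp_wave$fs`.
#' @param seed integer seed for noise and drift phases.
#' @param breath_truth optional [generate_breath_truth()] table to attach.
#' @return a [raw_channel_set()] with `truth = list(breaths, beats)`.
#' @export
render_channels <- function(resp_wave, beat_truth, mix = channel_mix(),
                            fs = 100, seed = 1L, breath_truth = NULL) {
  stopifnot(inherits(mix, "channel_mix"))
  if (!is.null(resp_wave) && !isTRUE(all.equal(resp_wave$fs, fs)))
    stop("resp_wave sampling rate differs from fs")
  n <- if (!is.null(resp_wave)) length(resp_wave$samples) else
    floor(attr(beat_truth, "duration") * fs) + 1L
  t <- (seq_len(n) - 1L) / fs
  resp <- if (!is.null(resp_wave)) resp_wave$samples else numeric(n)
  heart <- if (!is.null(beat_truth) && nrow(beat_truth) >= 2)
    render_heartbeat(beat_truth, fs, (n - 1L) / fs)$samples[seq_len(n)]
  else numeric(n)
  chans <- with_seed(seed, {
    lapply(mix, function(m) {
      phi0 <- runif(1, 0, 2 * pi)
      m$resp_gain * resp + m$heart_gain * heart +
        m$drift_amp * sin(2 * pi * m$drift_freq * t + phi0) +
        m$noise_sd * rnorm(n)
    })
  })
  raw_channel_set(chans, fs = fs, t0 = 0,
                  truth = list(breaths = breath_truth, beats = beat_truth))
}
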