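#' Simulate one recording session
#'
#' Generates breath truth, respiration-coupled beat truth and (optionally) the
#' four mixed baseband channels for a single routine.
#'
#' @param cardiac a [cardiac_params()]; `resp` a [resp_params()].
#' @param resp respiration parameters.
#' @param mix a [channel_mix()].
#' @param duration session length, s.
#' @param fs sampling rate, Hz.
#' @param seed integer seed.
#' @param render if `FALSE`, skip waveform/channel rendering and return the
#'   truth event series only (fast path for protocol-level experiments).
#' @return list with `breaths`, `beats` and (when rendered) `raw`, a
#'   [raw_channel_set()] with the truth attached.
#' @export
simulate_session <- function(cardiac = cardiac_params(),
                             resp = resp_params(), mix = channel_mix(),
                             duration = 300, fs = 100, seed = 1L,
                             render = TRUE) {
  breaths <- generate_breath_truth(resp, duration, seed = child_seed(seed, 1))
  beats <- generate_beat_truth(cardiac, breath_phase(breaths), duration,
                               seed = child_seed(seed, 2))
  out <- list(breaths = breaths, beats = beats)
  if (render) {
    rw <- render_respiration(breaths, fs)
    out$raw <- render_channels(rw, beats, mix, fs,
                               seed = child_seed(seed, 3),
                               breath_truth = breaths)
  }
  out
}

#' Default R-to-A state shift
#'
#' Additive parameter shifts applied to a subject's relaxed-state baseline to
#' obtain the attentive-state parameters. Effect sizes are free generator
#' inputs (the attentive state raises heart and respiration rate, damps
#' beat-to-beat variability, shortens relative inspiration and suppresses
#' end-expiratory pauses); they are not estimates of any study's physiology.
#'
#' @return named list of additive deltas on [cardiac_params()] /
#'   [resp_params()] fields.
#' @export
default_state_shift <- function() {
  list(mean_hr = 3, hr_sd = -0.3, lf_amp = 0, hf_amp = -0.01,
       mean_rr = 2, rr_sd = 0.3, ii_fraction = -0.05, pause_prob = -0.08,
       iv_cv = -0.03)
}

# Apply an additive shift spec to (cardiac, resp) pairs, clipping to the
# constructors' admissible ranges.
apply_state_shift <- function(cardiac, resp, shift) {
  cf <- unclass(cardiac); rf <- unclass(resp)
  for (f in intersect(names(shift), names(cf))) cf[[f]] <- cf[[f]] + shift[[f]]
  for (f in intersect(names(shift), names(rf))) rf[[f]] <- rf[[f]] + shift[[f]]
  cf$mean_hr <- min(max(cf$mean_hr, 45), 115)
  cf$hr_sd <- max(cf$hr_sd, 0); cf$hf_amp <- max(cf$hf_amp, 0)
  rf$mean_rr <- min(max(rf$mean_rr, 6), 40)
  rf$rr_sd <- max(rf$rr_sd, 0)
  rf$ii_fraction <- min(max(rf$ii_fraction, 0.05), 0.95)
  rf$pause_prob <- min(max(rf$pause_prob, 0), 1)
  rf$iv_cv <- max(rf$iv_cv, 0)
  list(cardiac = do.call(cardiac_params, cf), resp = do.call(resp_params, rf))
}

# Draw one subject's relaxed-state baseline around the cohort means. The
# between-subject spread deliberately exceeds the default R->A shift so that
# subject identity dominates state in pooled feature space.
draw_baseline <- function() {
  clip <- function(x, lo, hi) min(max(x, lo), hi)
  cardiac <- cardiac_params(
    mean_hr = clip(rnorm(1, 62, 7), 50, 95),
    hr_sd = clip(rnorm(1, 1.5, 0.4), 0.5, 3),
    lf_amp = clip(rnorm(1, 0.03, 0.008), 0.005, 0.06),
    hf_amp = clip(rnorm(1, 0.04, 0.01), 0.005, 0.08),
    harmonic2_rel_amp = clip(rnorm(1, 0.5, 0.1), 0.2, 0.9))
  resp <- resp_params(
    mean_rr = clip(rnorm(1, 14, 2.5), 9, 22),
    rr_sd = clip(rnorm(1, 1.2, 0.3), 0.4, 2.5),
    ii_fraction = clip(rnorm(1, 0.40, 0.05), 0.25, 0.55),
    pause_prob = clip(rnorm(1, 0.15, 0.07), 0, 0.4),
    iv_cv = clip(rnorm(1, 0.12, 0.04), 0.02, 0.3))
  list(cardiac = cardiac, resp = resp)
}

#' Simulate a two-routine cohort
#'
#' For each subject, draws a relaxed-state baseline around the cohort means,
#' applies the R-to-A state shift, and simulates a relaxed session, an
#' attentive session and the attentive-routine clock-task log. Identical seeds
#' reproduce the cohort bit-for-bit.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param seed integer master seed; per-subject seeds are derived from it.
#' @param state_shift_spec additive R-to-A parameter shifts (see
#'   [default_state_shift()]); an all-zero list yields non-separable states.
#' @param durations named vector `c(R =, A =)` of session lengths, s.
#' @param fs sampling rate, Hz.
#' @param mix a [channel_mix()] shared by all subjects.
#' @param render_signals if `FALSE`, generate truth event series and task logs
#'   only (no waveforms), for fast protocol-level experiments.
#' @param responder a [responder_model()] for the task log.
#' @return list of class `cohort`; one element per subject with fields
#'   `profile`, `R`, `A` (each a [simulate_session()] result) and `task_log`.
#' @export
generate_cohort <- function(n_subjects, seed = 1L,
                            state_shift_spec = default_state_shift(),
                            durations = c(R = 300, A = 390), fs = 100,
                            mix = channel_mix(), render_signals = TRUE,
                            responder = responder_model()) {
  stopifnot(n_subjects >= 1)
  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    si <- child_seed(seed, i)
    base <- with_seed(si, draw_baseline())
    shifted <- apply_state_shift(base$cardiac, base$resp, state_shift_spec)
    profile <- withCallingHandlers(
      subject_profile(i, params_R = base, params_A = shifted, mix = mix,
                      seed = si),
      warning = function(w) invokeRestart("muffleWarning"))
    R <- simulate_session(base$cardiac, base$resp, mix,
                          duration = durations[["R"]], fs = fs,
                          seed = child_seed(si, 10), render = render_signals)
    A <- simulate_session(shifted$cardiac, shifted$resp, mix,
                          duration = durations[["A"]], fs = fs,
                          seed = child_seed(si, 20), render = render_signals)
    task_log <- generate_task_log(durations[["A"]], responder = responder,
                                  seed = child_seed(si, 30))
    subjects[[i]] <- list(profile = profile, R = R, A = A,
                          task_log = task_log)
  }
  structure(subjects, class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d subjects, R/A sessions%s\n", length(x),
              if (!is.null(x[[1]]$R$raw)) " with rendered channels" else
                " (truth events only)"))
  invisible(x)
}
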