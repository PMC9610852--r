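#' Cardiac generator parameters
#'
#' Parameter set for the synthetic heartbeat process: mean heart rate and its
#' beat-to-beat variability, the depths of the low-frequency (Mayer-wave-like,
#' ~0.1 Hz) and respiration-coupled (RSA) inter-beat-interval modulations, and
#' the relative amplitude of the second harmonic of the mechanical heartbeat
#' waveform. The defaults describe a resting adult with a heart rate centred
#' near 59 beats/min spanning roughly 56--62 beats/min.
#'
#' @param mean_hr mean heart rate, beats/min; must lie in `[45, 115]`.
#' @param hr_sd beat-to-beat heart-rate standard deviation, beats/min (>= 0).
#' @param lf_amp,hf_amp dimensionless IBI modulation depths for the 0.1 Hz
#'   low-frequency component and the respiration-coupled (RSA) component.
#' @param lf_freq low-frequency modulation frequency, Hz.
#' @param harmonic2_rel_amp amplitude of the second heartbeat harmonic relative
#'   to the fundamental (> 0); the second harmonic is weaker but sharper and is
#'   what beat timing is measured on downstream.
#' @return object of class `cardiac_params`.
#' @export
cardiac_params <- function(mean_hr = 59, hr_sd = 1.5, lf_amp = 0.03,
                           hf_amp = 0.04, lf_freq = 0.1,
                           harmonic2_rel_amp = 0.5) {
  stop_if_not_scalar(mean_hr, "mean_hr", 45, 115)
  stop_if_not_scalar(hr_sd, "hr_sd", 0)
  stop_if_not_scalar(lf_amp, "lf_amp", 0)
  stop_if_not_scalar(hf_amp, "hf_amp", 0)
  stop_if_not_scalar(lf_freq, "lf_freq", 0)
  if (harmonic2_rel_amp <= 0) stop("'harmonic2_rel_amp' must be > 0")
  structure(list(mean_hr = mean_hr, hr_sd = hr_sd, lf_amp = lf_amp,
                 hf_amp = hf_amp, lf_freq = lf_freq,
                 harmonic2_rel_amp = harmonic2_rel_amp),
            class = "cardiac_params")
}

#' Respiration generator parameters
#'
#' Parameter set for the synthetic breathing process: mean respiration rate and
#' breath-to-breath rate variability, the fraction of each breath spent
#' inspiring, the probability and duration of a flat end-expiratory pause, and
#' the coefficient of variation of breath amplitude.
#'
#' @param mean_rr mean respiration rate, breaths/min; must lie in `[6, 40]`.
#' @param rr_sd breath-to-breath respiration-rate standard deviation,
#'   breaths/min.
#' @param ii_fraction mean fraction of the inter-respiration interval occupied
#'   by inspiration (strictly between 0 and 1).
#' @param pause_prob probability that a breath ends with a flat end-expiratory
#'   pause.
#' @param pause_dur pause duration, s.
#' @param iv_cv coefficient of variation of the inspiratory amplitude.
#' @return object of class `resp_params`.
#' @export
resp_params <- function(mean_rr = 14, rr_sd = 1.2, ii_fraction = 0.4,
                        pause_prob = 0.15, pause_dur = 0.8, iv_cv = 0.12) {
  stop_if_not_scalar(mean_rr, "mean_rr", 6, 40)
  stop_if_not_scalar(rr_sd, "rr_sd", 0)
  if (ii_fraction <= 0 || ii_fraction >= 1)
    stop("'ii_fraction' must be in (0, 1)")
  stop_if_not_scalar(pause_prob, "pause_prob", 0, 1)
  stop_if_not_scalar(pause_dur, "pause_dur", 0)
  stop_if_not_scalar(iv_cv, "iv_cv", 0)
  structure(list(mean_rr = mean_rr, rr_sd = rr_sd, ii_fraction = ii_fraction,
                 pause_prob = pause_prob, pause_dur = pause_dur, iv_cv = iv_cv),
            class = "resp_params")
}

#' Channel mixing model
#'
#' Gains, noise and baseline drift for the four baseband channels
#' (`thorax_amp`, `thorax_phase`, `abd_amp`, `abd_phase`). The thorax channels
#' default to the stronger heartbeat coupling and the abdomen channels to the
#' stronger respiration coupling, mirroring sensor placement.
#'
#' @param channels named list with one entry per channel, each a list with
#'   fields `resp_gain`, `heart_gain`, `noise_sd`, `drift_amp`, `drift_freq`
#'   (drift frequency must be below 0.05 Hz). Missing fields take the defaults.
#' @return object of class `channel_mix`: a named list of 4 channel specs.
#' @export
channel_mix <- function(channels = list()) {
  nm <- c("thorax_amp", "thorax_phase", "abd_amp", "abd_phase")
  defaults <- list(
    thorax_amp   = list(resp_gain = 1.0, heart_gain = 0.50, noise_sd = 0.05,
                        drift_amp = 0.3, drift_freq = 0.02),
    thorax_phase = list(resp_gain = 0.8, heart_gain = 0.40, noise_sd = 0.06,
                        drift_amp = 0.3, drift_freq = 0.015),
    abd_amp      = list(resp_gain = 1.5, heart_gain = 0.10, noise_sd = 0.05,
                        drift_amp = 0.4, drift_freq = 0.02),
    abd_phase    = list(resp_gain = 1.2, heart_gain = 0.08, noise_sd = 0.07,
                        drift_amp = 0.4, drift_freq = 0.012))
  bad <- setdiff(names(channels), nm)
  if (length(bad)) stop("unknown channel(s): ", paste(bad, collapse = ", "))
  mix <- defaults
  for (ch in names(channels)) mix[[ch]] <- modifyList(mix[[ch]], channels[[ch]])
  for (ch in nm) {
    m <- mix[[ch]]
    if (m$resp_gain < 0 || m$heart_gain < 0 || m$noise_sd < 0 ||
        m$drift_amp < 0)
      stop("gains, noise_sd and drift_amp must be >= 0 (channel ", ch, ")")
    if (m$drift_freq >= 0.05) stop("drift_freq must be < 0.05 Hz")
  }
  structure(mix, class = "channel_mix")
}

#' Subject profile for cohort simulation
#'
#' Bundles the relaxed-state (R) and attentive-state (A) cardiorespiratory
#' parameter pairs, the channel mix and the subject seed. Equal R and A
#' parameters are allowed (the null, non-separable subject) but flagged with a
#' warning, because state separability is a generator input.
#'
#' @param subject_id identifier (coerced to character).
#' @param params_R,params_A lists `list(cardiac =, resp =)` holding
#'   [cardiac_params()] / [resp_params()] objects for each routine.
#' @param mix a [channel_mix()].
#' @param seed integer seed for the subject's random draws.
#' @return object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, params_R, params_A,
                            mix = channel_mix(), seed = 1L) {
  stopifnot(inherits(params_R$cardiac, "cardiac_params"),
            inherits(params_R$resp, "resp_params"),
            inherits(params_A$cardiac, "cardiac_params"),
            inherits(params_A$resp, "resp_params"),
            inherits(mix, "channel_mix"))
  if (identical(unclass(params_R$cardiac), unclass(params_A$cardiac)) &&
      identical(unclass(params_R$resp), unclass(params_A$resp)))
    warning("params_R and params_A are identical: R/A states are not separable",
            call. = FALSE)
  structure(list(subject_id = as.character(subject_id), params_R = params_R,
                 params_A = params_A, mix = mix, seed = as.integer(seed)),
            class = "subject_profile")
}

#' @export
print.cardiac_params <- function(x, ...) {
  cat(sprintf(
    "cardiac_params: mean HR %.1f bpm (sd %.2f), LF %.3f @ %.2f Hz, RSA %.3f, h2 %.2f\n",
    x$mean_hr, x$hr_sd, x$lf_amp, x$lf_freq, x$hf_amp, x$harmonic2_rel_amp))
  invisible(x)
}

#' @export
print.resp_params <- function(x, ...) {
  cat(sprintf(
    "resp_params: mean RR %.1f brpm (sd %.2f), II/IRI %.2f, pause p=%.2f (%.1f s), IV cv %.2f\n",
    x$mean_rr, x$rr_sd, x$ii_fraction, x$pause_prob, x$pause_dur, x$iv_cv))
  invisible(x)
}
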