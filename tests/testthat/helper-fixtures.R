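# Shared fixtures, built once per test run.

.fixt <- new.env(parent = emptyenv())

# A default-parameter rendered session with ground truth, cached.
fixture_session <- function(seed = 301, duration = 300) {
  key <- paste0("s", seed, "_", duration)
  if (is.null(.fixt[[key]])) {
    bt <- generate_breath_truth(resp_params(), duration, seed = seed)
    rw <- render_respiration(bt, 100)
    beat <- generate_beat_truth(cardiac_params(), breath_phase(bt), duration,
                                seed = seed + 1)
    raw <- render_channels(rw, beat, channel_mix(), 100, seed = seed + 2,
                           breath_truth = bt)
    .fixt[[key]] <- list(breaths = bt, resp_wave = rw, beats = beat,
                         raw = raw)
  }
  .fixt[[key]]
}

# Epoch-feature table from generator truth events (no waveform chain), for
# protocol-level tests.
truth_feature_table <- function(cohort) {
  tabs <- list()
  for (i in seq_along(cohort)) {
    for (lab in c("R", "A")) {
      ses <- cohort[[i]][[lab]]
      tabs[[paste(i, lab)]] <- feature_matrix(
        truth_beat_series(ses$beats), truth_breath_series(ses$breaths),
        if (lab == "R") 290 else 390, epoch_spec(), label = lab,
        subject_id = cohort[[i]]$profile$subject_id)
    }
  }
  tab <- do.call(rbind, tabs)
  class(tab) <- c("epoch_features", "data.frame")
  tab
}

zero_shift <- function() list(mean_hr = 0, hr_sd = 0, lf_amp = 0, hf_amp = 0,
                              mean_rr = 0, rr_sd = 0, ii_fraction = 0,
                              pause_prob = 0, iv_cv = 0)
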