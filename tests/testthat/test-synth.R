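test_that("breath truth honours zero-variance and bound contracts", {
  bt <- generate_breath_truth(resp_params(mean_rr = 15, rr_sd = 0,
                                          pause_prob = 0), 120, seed = 1)
  expect_true(all(abs(bt$iri[-1] - 4.0) < 1e-12))
  expect_error(resp_params(mean_rr = 5), "mean_rr")
  expect_error(generate_breath_truth(list(mean_rr = 5), 120), "mean_rr")
  expect_error(generate_breath_truth(resp_params(mean_rr = 15), 10),
               "3 breath periods")
})

test_that("breath interval draws match the generator's own distribution", {
  bt <- generate_breath_truth(resp_params(mean_rr = 15, rr_sd = 1), 300,
                              seed = 7)
  rates <- 60 / bt$iri[-1]
  sem <- sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - 15), 3 * sem + 0.2)
})

test_that("rendered respiration places maxima at te with amplitude iv", {
  tr <- breath_truth(tb = 2, te = 4, iv = 1, duration = 8)
  w <- render_respiration(tr, 100)
  t_argmax <- (which.max(w$samples) - 1) / 100
  expect_lt(abs(t_argmax - 4), 1 / 100 + 1e-9)
  r <- function(tt) w$samples[round(tt * 100) + 1]
  expect_lt(abs((r(4) - r(2)) - 1), 0.01)
  expect_error(render_respiration(tr, 5), "undersample")
})

test_that("end-expiratory pauses are flat", {
  tr <- breath_truth(tb = c(2, 8), te = c(4, 10), iv = 1, pause = c(FALSE,
                                                                    TRUE),
                     pause_dur = 1.5, duration = 12)
  w <- render_respiration(tr, 100)
  # pause occupies [tb2 - 1.5, tb2] = [6.5, 8]
  seg <- w$samples[(6.6 * 100):(7.9 * 100)]
  expect_lt(max(abs(diff(seg))) * 100, 1e-6)
})

test_that("symmetric pause-free breathing approaches a sinusoid", {
  bt <- generate_breath_truth(resp_params(mean_rr = 15, rr_sd = 0,
                                          ii_fraction = 0.5, pause_prob = 0,
                                          iv_cv = 0), 120, seed = 1)
  w <- render_respiration(bt, 100)
  n <- length(w$samples)
  t <- (seq_len(n) - 1) / 100
  sel <- t >= bt$tb[1] & t <= bt$te[nrow(bt)]
  x <- w$samples[sel]; tt <- t[sel]
  X <- cbind(1, sin(2 * pi * 0.25 * tt), cos(2 * pi * 0.25 * tt))
  fit <- lm.fit(X, x)
  expect_gt(cor(X %*% fit$coefficients, x), 0.99)
})

test_that("beat truth honours zero-modulation and positivity contracts", {
  bt <- generate_beat_truth(cardiac_params(mean_hr = 60, hr_sd = 0,
                                           lf_amp = 0, hf_amp = 0), NULL,
                            60, seed = 1)
  expect_true(all(abs(bt$ibi[-nrow(bt)] - 1.0) < 1e-12))
  expect_error(
    generate_beat_truth(cardiac_params(mean_hr = 60, lf_amp = 0.6,
                                       hf_amp = 0.5), NULL, 60),
    "non-positive IBI")
})

test_that("RSA coupling creates an HF tachogram peak at the breathing rate", {
  rb <- generate_breath_truth(resp_params(mean_rr = 15, rr_sd = 0.3), 300,
                              seed = 3)
  bt <- generate_beat_truth(cardiac_params(mean_hr = 60, hr_sd = 0.2,
                                           lf_amp = 0, hf_amp = 0.05),
                            breath_phase(rb), 300, seed = 4)
  keep <- !is.na(bt$ibi)
  # periodogram oracle on the interpolated tachogram
  g <- seq(min(bt$time), max(bt$time[keep]), by = 0.25)
  yi <- approx(bt$time[keep], bt$ibi[keep], xout = g)$y
  sp <- Mod(fft(yi - mean(yi)))^2
  f <- (seq_along(sp) - 1) / (length(sp) * 0.25)
  hf <- f >= 0.15 & f <= 0.4
  fpk <- f[hf][which.max(sp[hf])]
  expect_lt(abs(fpk - 0.25), 0.03)
  # and the HF peak dominates the LF band
  expect_gt(max(sp[hf]), max(sp[f >= 0.04 & f < 0.15]))
})

test_that("LF tachogram power grows monotonically with lf_amp", {
  pw <- vapply(c(0.01, 0.03, 0.06), function(a) {
    bt <- generate_beat_truth(cardiac_params(mean_hr = 60, hr_sd = 0.2,
                                             lf_amp = a, hf_amp = 0), NULL,
                              300, seed = 5)
    keep <- !is.na(bt$ibi)
    lomb_band_power(bt$time[keep], bt$ibi[keep], 0.04, 0.15)
  }, 1)
  expect_true(all(diff(pw) > 0))
})

test_that("channel mixing reduces to scaled respiration in the clean limit", {
  s <- fixture_session()
  mix <- channel_mix(list(thorax_amp = list(noise_sd = 0, heart_gain = 0,
                                            drift_amp = 0, resp_gain = 2)))
  raw <- render_channels(s$resp_wave, s$beats, mix, 100, seed = 1)
  expect_equal(raw$channels$thorax_amp, 2 * s$resp_wave$samples,
               tolerance = 1e-12)
})

test_that("baseline drift is removed by the respiration high-pass", {
  mix <- channel_mix(list(thorax_amp = list(noise_sd = 0, heart_gain = 0,
                                            resp_gain = 0, drift_amp = 1,
                                            drift_freq = 0.01)))
  s <- fixture_session()
  raw <- render_channels(s$resp_wave, s$beats, mix, 100, seed = 2)
  x <- raw$channels$thorax_amp
  hp <- vigilwave:::filt_zerophase_iir(design_resp_highpass(100), x, 100)
  # ignore edge transients of the 0.05 Hz high-pass
  core <- seq(3000, length(x) - 3000)
  expect_lt(sqrt(mean(hp[core]^2)), 0.05 * sqrt(mean(x[core]^2)))
})

test_that("task log outcomes follow the clock-task semantics", {
  quiet <- responder_model(miss_prob = 0, false_press_prob = 0)
  lg <- generate_task_log(500, jump_prob = 0, responder = quiet, seed = 1)
  expect_identical(sum(lg$outcome != "none"), 0L)
  perfect <- generate_task_log(600, jump_prob = 0.1, responder = quiet,
                               seed = 2)
  sc <- score_events(perfect)
  expect_identical(unname(sc$counts["W"] + sc$counts["M"]), 0L)
  expect_equal(sc$pocr, 1)
  # rt present iff responded, rt <= max_rt, outcomes consistent
  lg2 <- generate_task_log(2000, seed = 3)
  expect_identical(is.na(lg2$rt), !lg2$responded)
  expect_true(all(lg2$rt[lg2$responded] <= attr(lg2, "max_rt")))
  expect_true(all(lg2$outcome[lg2$is_jump & lg2$responded] == "correct"))
  expect_true(all(lg2$outcome[lg2$is_jump & !lg2$responded] == "missed"))
  expect_error(generate_task_log(100, jump_prob = 1.4), "jump_prob")
})

test_that("cohort generation is bit-stable under a fixed seed", {
  a <- generate_cohort(1, seed = 5, durations = c(R = 120, A = 150))
  b <- generate_cohort(1, seed = 5, durations = c(R = 120, A = 150))
  expect_identical(a, b)
})

test_that("default intervals stay in the physiological bands", {
  for (seed in c(21, 22, 23)) {
    bt <- generate_breath_truth(resp_params(), 300, seed = seed)
    expect_true(all(bt$iri[-1] > 60 / 40 & bt$iri[-1] < 60 / 6))
    hb <- generate_beat_truth(cardiac_params(),
                              breath_phase(bt), 300, seed = seed)
    ibi <- hb$ibi[!is.na(hb$ibi)]
    expect_true(all(ibi > 60 / 115 & ibi < 60 / 45))
  }
})

test_that("truth te lie within one sample of a rendered local maximum", {
  s <- fixture_session()
  x <- s$resp_wave$samples
  is_local_max <- function(j) x[j] >= x[j - 1] && x[j] >= x[j + 1]
  for (tt in s$breaths$te[2:(nrow(s$breaths) - 1)]) {
    i <- round(tt * 100) + 1
    expect_true(any(vapply((i - 1):(i + 1), is_local_max, TRUE)))
  }
})
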