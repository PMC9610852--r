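test_that("MAC peaks recover sinusoid maxima and ignore monotone ramps", {
  t <- (0:5999) / 100
  x <- sin(2 * pi * 0.25 * t)
  pk <- mac_peaks(x, 100, window = 2)
  expect_length(pk, 15)
  expect_true(all(abs(pk - (1 + 4 * (0:14))) <= 0.01 + 1e-9))
  set.seed(77)
  noisy <- x + rnorm(length(x), sd = 0.1)
  pk2 <- mac_peaks(noisy, 100, window = 2)
  expect_length(pk2, 15)
  expect_true(all(abs(pk2 - (1 + 4 * (0:14))) <= 0.1))
  expect_length(mac_peaks(seq(0, 1, length.out = 600), 100, window = 2), 0)
  expect_error(mac_peaks(x[1:100], 100, window = 2), "longer than record")
})

test_that("MAC peak count matches a brute-force local-maximum oracle", {
  # quasi-periodic records <= 30 s: exhaustive search for samples that are the
  # strict maximum of their +/- half-window neighbourhood (away from the
  # edges) must find the same number of peaks as the MAC algorithm
  rp <- resp_params()
  for (seed in 1:8) {
    bt <- generate_breath_truth(rp, 30, seed = seed)
    x <- render_respiration(bt, 100)$samples
    win <- 0.7 * 60 / rp$mean_rr
    pk <- mac_peaks(x, 100, window = win)
    h <- round(win * 100 / 2); m <- round(win * 100); n <- length(x)
    is_max <- vapply((m + 1):(n - m), function(i)
      x[i] > max(x[c((i - h):(i - 1), (i + 1):(i + h))]), TRUE)
    expect_identical(length(pk), sum(is_max))
  }
})

test_that("detections are amplitude-scale invariant", {
  t <- (0:5999) / 100
  set.seed(5)
  x <- sin(2 * pi * 0.25 * t) + rnorm(6000, sd = 0.05)
  expect_identical(mac_peaks(x, 100, 2), mac_peaks(3.7 * x, 100, 2))
  w1 <- vital_waveform(x, 100, "respiration")
  w2 <- vital_waveform(2.5 * x, 100, "respiration")
  expect_identical(detect_inspire_end(w1), detect_inspire_end(w2))
})

test_that("a pure 2 Hz second harmonic yields 1 s IBI and 60 beats/min", {
  t <- (0:11999) / 100
  h2 <- vital_waveform(sin(2 * pi * 2 * t), 100, "heartbeat_h2")
  h2$f_dom <- 1
  bs <- detect_ibi(h2)
  expect_true(all(abs(bs$ibi - 1.0) < 0.011))
  expect_equal(mean(60 / bs$ibi), 60, tolerance = 0.01)
  short <- vital_waveform(sin(2 * pi * 2 * (0:50) / 100), 100,
                          "heartbeat_h2")
  short$f_dom <- 1
  expect_error(detect_ibi(short), "fewer than 3")
})

test_that("detected IBI tracks generator truth closely", {
  s <- fixture_session()
  hb <- select_best_channel(s$raw, "heartbeat")
  h2 <- refilter_second_harmonic(hb)
  bs <- clean_ibi(detect_ibi(h2))
  truth_hr <- mean(60 / s$beats$ibi, na.rm = TRUE)
  expect_lt(abs(mean(60 / bs$ibi) - truth_hr), 1)
  tf <- approxfun(s$beats$time[-nrow(s$beats)],
                  s$beats$ibi[-nrow(s$beats)], rule = 2)
  expect_lt(sqrt(mean((bs$ibi - tf(bs$time))^2)), 0.02)
})

test_that("instantaneous rate follows a programmed ramp with small lag", {
  # HR ramps 55 -> 65 beats/min over 300 s via a time-varying IBI
  duration <- 300
  times <- 0.3; repeat {
    hr <- 55 + 10 * times[length(times)] / duration
    nxt <- times[length(times)] + 60 / hr
    if (nxt > duration) break
    times <- c(times, nxt)
  }
  bt <- data.frame(time = times, ibi = c(diff(times), NA))
  attr(bt, "duration") <- duration
  class(bt) <- c("beat_truth", "data.frame")
  raw <- render_channels(NULL, bt, channel_mix(), 100, seed = 9)
  hb <- select_best_channel(raw, "heartbeat")
  h2 <- refilter_second_harmonic(hb, halfwidth = 0.8)
  bs <- detect_ibi(h2)
  hr_det <- 60 / bs$ibi
  hr_true <- 55 + 10 * bs$time / duration
  core <- bs$time > 10 & bs$time < duration - 10
  err <- hr_det[core] - hr_true[core]
  expect_lt(sqrt(mean(err^2)), 1)
  # lag below 2 s: shifting truth by 2 s must fit worse than by 0 s
  rss <- function(lag) sum((hr_det[core] - (55 + 10 * (bs$time[core] - lag) /
                                              duration))^2)
  expect_lt(rss(0), rss(2))
})

test_that("inspire-begin lands on the trough of a clean sinusoid", {
  t <- (0:5999) / 100
  w <- vital_waveform(sin(2 * pi * 0.25 * t), 100, "respiration")
  te <- detect_inspire_end(w)
  tb <- detect_inspire_begin(w, te)
  expect_true(all(abs((te[-1] - tb) - 2) < 0.05))
  expect_true(all(tb > te[-length(te)] & tb < te[-1]))
})

test_that("comparable-depth candidates resolve to the pause end", {
  # breath with a flat end-expiratory pause followed by a shallow dip:
  # candidates of comparable depth, the rule picks the one nearest te
  fs <- 100
  t <- seq(0, 12, by = 1 / fs)
  x <- numeric(length(t))
  seg <- function(lo, hi) t >= lo & t < hi
  x[seg(0, 1)] <- 0.5 * (1 - cos(pi * t[seg(0, 1)] / 1))          # rise te1=1
  x[seg(1, 3.5)] <- 0.5 * (1 + cos(pi * (t[seg(1, 3.5)] - 1) / 2.5))
  x[seg(3.5, 5)] <- 0                                             # pause
  dip <- seg(5, 5.6)
  x[dip] <- -0.03 * sin(pi * (t[dip] - 5) / 0.6)                  # shallow dip
  rise2 <- t >= 5.6
  x[rise2] <- 0.5 * (1 - cos(pi * pmin(t[rise2] - 5.6, 2) / 2))   # te2 = 7.6
  w <- vital_waveform(x, fs, "respiration")
  tb <- detect_inspire_begin(w, c(1, 7.6))
  # nearest-te candidate: pause end / dip region, not the pause start
  expect_gt(tb, 4.8)
  expect_lt(tb, 5.9)
})

test_that("a deep secondary minimum defeats shallow ripple candidates", {
  # expiration with a small ripple (~40% depth) then a deep true trough:
  # depth ratio >= 2, the rule picks the deepest candidate
  fs <- 100
  t <- seq(0, 10, by = 1 / fs)
  x <- cos(2 * pi * t / 8)                     # slow wave, peaks at 0 and 8
  ripple <- t >= 1.2 & t <= 2.0
  x[ripple] <- x[ripple] + 0.55 * sin(pi * (t[ripple] - 1.2) / 0.8)^2
  w <- vital_waveform(x, fs, "respiration")
  tb <- detect_inspire_begin(w, c(0, 8))
  expect_lt(abs(tb - 4), 0.35)                 # deep trough at t = 4
})

test_that("breath series arithmetic follows the interval definitions", {
  fs <- 100
  t <- seq(0, 10, by = 1 / fs)
  x <- 0.5 + 0.5 * cos(pi * t / 2)             # maxima at 4, 8; troughs 2, 6
  w <- vital_waveform(x, fs, "respiration")
  bs <- build_breath_series(w, te = c(4, 8), tb = c(2, 6))
  expect_equal(nrow(bs), 1L)
  expect_equal(bs$iri, 4)
  expect_equal(bs$ii, 2)
  expect_equal(bs$ei, 2)
  expect_equal(bs$iv, 1, tolerance = 0.01)
  expect_equal(bs$ii + bs$ei, bs$iri)
})

test_that("full breath recovery on a rendered session is accurate", {
  s <- fixture_session()
  resp <- select_best_channel(s$raw, "respiration")
  te <- detect_inspire_end(resp)
  expect_identical(length(te), nrow(s$breaths))
  tb <- detect_inspire_begin(resp, te)
  bs <- build_breath_series(resp, te, tb)
  expect_true(all(bs$tb > head(bs$te - bs$iri, nrow(bs))))
  idx <- vapply(bs$te, function(tt) which.min(abs(s$breaths$te - tt)), 1L)
  expect_lt(sqrt(mean((bs$ii - s$breaths$ii[idx])^2)), 0.15)
  expect_lt(sqrt(mean((bs$ei - s$breaths$ei[idx])^2)), 0.15)
  expect_true(all(abs(bs$ii + bs$ei - bs$iri) < 1e-9))
})
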