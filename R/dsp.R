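#' SNR band specification
#'
#' Frequency bands for the periodogram SNR score: `f1` is the desired-signal
#' band (closed), `f2` the low-side noise band (closed below, open above) and
#' `f3` the high-side noise band (open below, closed above). The built-in
#' specs are heartbeat `f1 = [0.8, 2]`, `f2 = [0.05, 0.8)`, `f3 = (2, 50]` Hz
#' and respiration `f1 = [0.1, 0.7]`, `f2 = [0.05, 0.1)`, `f3 = (0.7, 50]` Hz.
#'
#' @param kind `"respiration"` or `"heartbeat"`, or pass explicit bands.
#' @param f1,f2,f3 length-2 interval bounds, Hz.
#' @return object of class `band_spec`.
#' @export
band_spec <- function(kind = c("respiration", "heartbeat"), f1 = NULL,
                      f2 = NULL, f3 = NULL) {
  if (is.null(f1)) {
    kind <- match.arg(kind)
    if (kind == "heartbeat") {
      f1 <- c(0.8, 2); f2 <- c(0.05, 0.8); f3 <- c(2, 50)
    } else {
      f1 <- c(0.1, 0.7); f2 <- c(0.05, 0.1); f3 <- c(0.7, 50)
    }
  }
  if (!(f2[2] <= f1[1] && f1[2] <= f3[1]))
    stop("bands must be ordered f2 below f1 below f3 and disjoint")
  structure(list(f1 = f1, f2 = f2, f3 = f3), class = "band_spec")
}

# One-sided periodogram on a rectangular window over the whole record.
# Returns bin-center frequencies and per-bin power (variance units), so that
# sum(power) equals the mean square of the signal (Parseval).
periodogram_power <- function(x, fs) {
  n <- length(x)
  X <- fft(x)
  half <- floor(n / 2)
  p <- Mod(X[1:(half + 1)])^2 / n^2
  scale <- rep(2, half + 1)
  scale[1] <- 1
  if (n %% 2 == 0) scale[half + 1] <- 1
  list(freq = (0:half) * fs / n, power = p * scale)
}

# Dominant frequency of a waveform's periodogram within [lo, hi] Hz; NULL if
# the peak does not rise above `ratio` times the in-band median power.
dominant_frequency <- function(x, fs, lo, hi, ratio = 5) {
  pg <- periodogram_power(x - mean(x), fs)
  sel <- pg$freq >= lo & pg$freq <= hi
  if (!any(sel)) return(NULL)
  p <- pg$power[sel]; f <- pg$freq[sel]
  i <- which.max(p)
  floor_p <- median(p)
  if (floor_p > 0 && p[i] < ratio * floor_p) return(NULL)
  if (p[i] <= 0) return(NULL)
  f[i]
}

new_vital_waveform <- function(samples, fs, kind, source_channel = NA_character_,
                               snr_db = NA_real_, extras = list()) {
  structure(c(list(samples = samples, fs = fs, t0 = 0, kind = kind,
                   source_channel = source_channel, snr_db = snr_db), extras),
            class = c("vital_waveform", "waveform"))
}

#' Construct a vital waveform from samples
#'
#' Light constructor wrapping already-prepared samples as a `vital_waveform`
#' (useful for constructed fixtures and externally prepared traces). No
#' filtering or normalization is applied.
#'
#' @param samples numeric samples.
#' @param fs sampling rate, Hz.
#' @param kind `"respiration"`, `"heartbeat"` or `"heartbeat_h2"`.
#' @param t0 time of the first sample, s.
#' @return object of class `vital_waveform`.
#' @export
vital_waveform <- function(samples, fs = 100,
                           kind = c("respiration", "heartbeat",
                                    "heartbeat_h2"), t0 = 0) {
  kind <- match.arg(kind)
  w <- new_vital_waveform(as.numeric(samples), fs, kind)
  w$t0 <- t0
  w
}

#' @export
print.vital_waveform <- function(x, ...) {
  cat(sprintf("vital_waveform [%s]: %.1f s @ %g Hz%s%s\n", x$kind,
              length(x$samples) / x$fs, x$fs,
              if (!is.na(x$source_channel))
                paste0(", channel ", x$source_channel) else "",
              if (!is.na(x$snr_db)) sprintf(", SNR %.1f dB", x$snr_db) else ""))
  invisible(x)
}

# Shared preparation: zero-phase high-pass + Kaiser FIR low-pass, 60 s
# mean/RMS normalization, polyphase resampling to 100 Hz. `keep_wideband`
# additionally retains the high-passed (pre-low-pass) signal, normalized and
# resampled the same way: the second-harmonic re-filtering needs content
# above the heartbeat low-pass cutoff.
prepare_vital <- function(x, fs, hp_filt, lp_fc, kind, norm_window = 60,
                          fir_trans = 0.2, fir_atten_db = 60,
                          keep_wideband = FALSE) {
  if (inherits(x, "waveform")) { fs <- x$fs; x <- x$samples }
  if (sd(x) < 1e-12) stop("all-constant input: zero RMS, cannot normalize")
  hp <- filt_zerophase_iir(hp_filt, x, fs)
  b <- design_kaiser_lowpass(lp_fc, fs, trans = fir_trans,
                             atten_db = fir_atten_db)
  y <- filt_zerophase_fir(b, hp)
  nw <- round(norm_window * fs)
  if (nw > length(y)) {
    warning("record shorter than ", norm_window,
            " s: normalizing over the full record")
    nw <- length(y)
  }
  finish <- function(y) {
    head_y <- y[1:nw]
    y <- y - mean(head_y)
    r <- sqrt(mean((head_y - mean(head_y))^2))
    if (r < 1e-12) stop("zero RMS in the normalization window")
    y <- y / r
    if (!isTRUE(all.equal(fs, 100))) {
      pq <- rational_ratio(100, fs)
      y <- as.numeric(signal::resample(y, pq[1], pq[2]))
    }
    y
  }
  extras <- if (keep_wideband) list(wideband = finish(hp)) else list()
  new_vital_waveform(finish(y), 100, kind, extras = extras)
}

# Small-denominator rational p/q ~= a/b for the resampler.
rational_ratio <- function(a, b, max_den = 1000) {
  for (q in 1:max_den) {
    p <- a * q / b
    if (isTRUE(all.equal(p, round(p), tolerance = 1e-9)))
      return(c(round(p), q))
  }
  stop("cannot express ", a, "/", b, " as a small rational ratio")
}

#' Extract the respiration waveform from one channel
#'
#' Removes baseline with a zero-phase order-5 Butterworth high-pass (3 dB at
#' 0.05 Hz), suppresses heartbeat content with a Kaiser-window FIR low-pass
#' cut at 0.8 Hz, subtracts the mean of the first 60 s and divides by the RMS
#' of the same 60 s, then resamples to a uniform 100 Hz.
#'
#' @param x numeric channel samples or a `waveform`.
#' @param fs input sampling rate, Hz (ignored when `x` is a `waveform`).
#' @param norm_window normalization window, s; records shorter than this fall
#'   back to the full record with a warning.
#' @return a `vital_waveform` of kind `"respiration"` at 100 Hz.
#' @export
extract_respiration <- function(x, fs = 100, norm_window = 60) {
  prepare_vital(x, fs, design_resp_highpass(if (inherits(x, "waveform"))
    x$fs else fs), lp_fc = 0.8, kind = "respiration",
    norm_window = norm_window)
}

#' Extract the heartbeat waveform from one channel
#'
#' As [extract_respiration()], but with a third-order Butterworth high-pass
#' (3 dB at 0.7 Hz) and a Kaiser FIR low-pass cut at 1.9 Hz, passing the
#' heartbeat fundamental band.
#'
#' @inheritParams extract_respiration
#' @return a `vital_waveform` of kind `"heartbeat"` at 100 Hz.
#' @export
extract_heartbeat <- function(x, fs = 100, norm_window = 60) {
  prepare_vital(x, fs, design_heart_highpass(if (inherits(x, "waveform"))
    x$fs else fs), lp_fc = 1.9, kind = "heartbeat",
    norm_window = norm_window, keep_wideband = TRUE)
}

#' Periodogram SNR of a waveform
#'
#' Removes baseline with a zero-phase high-pass (3 dB at 0.08 Hz), computes
#' the rectangular-window periodogram of the whole record, integrates power
#' over the signal band `f1` and the noise bands `f2`, `f3` of `bands`, and
#' returns `10 * log10(P_f1 / (P_f2 + P_f3))`. A vanishing noise power yields
#' the capped maximum (+100 dB) with `capped = TRUE` rather than infinity.
#'
#' @param x numeric samples or a `waveform`/`vital_waveform`.
#' @param fs sampling rate, Hz.
#' @param bands a [band_spec()].
#' @return list with `snr_db`, `capped`, and the three band powers.
#' @export
compute_snr <- function(x, fs = 100, bands = band_spec("respiration")) {
  if (inherits(x, "waveform")) { fs <- x$fs; x <- x$samples }
  stopifnot(inherits(bands, "band_spec"))
  if (length(x) < 30 * fs) stop("need at least 30 s of data for SNR")
  if (bands$f3[2] > fs / 2 + 1e-9) stop("f3 upper edge exceeds fs/2")
  y <- filt_zerophase_iir(design_resp_highpass(fs, f3db = 0.08), x, fs)
  pg <- periodogram_power(y, fs)
  f <- pg$freq; p <- pg$power
  p1 <- sum(p[f >= bands$f1[1] & f <= bands$f1[2]])
  p2 <- sum(p[f >= bands$f2[1] & f < bands$f2[2]])
  p3 <- sum(p[f > bands$f3[1] & f <= bands$f3[2]])
  noise <- p2 + p3
  if (noise <= p1 * 1e-10 || 10 * log10(p1 / noise) > 100)
    return(list(snr_db = 100, capped = TRUE, p_f1 = p1, p_f2 = p2, p_f3 = p3))
  list(snr_db = 10 * log10(p1 / noise), capped = FALSE,
       p_f1 = p1, p_f2 = p2, p_f3 = p3)
}

#' Select the best channel for a vital sign
#'
#' Applies the kind-appropriate extraction to each of the four channels,
#' scores each result with [compute_snr()] under the kind's [band_spec()], and
#' returns the highest-SNR waveform. Ties break deterministically in the fixed
#' channel order `thorax_amp`, `thorax_phase`, `abd_amp`, `abd_phase`.
#' Channels whose extraction fails (degenerate input) are skipped; if all four
#' fail, an error is raised.
#'
#' @param raw a [raw_channel_set()].
#' @param kind `"respiration"` or `"heartbeat"`.
#' @return the winning `vital_waveform` with `source_channel` and `snr_db`
#'   set; per-channel scores are attached as attribute `all_snr_db`.
#' @export
select_best_channel <- function(raw, kind = c("respiration", "heartbeat")) {
  kind <- match.arg(kind)
  stopifnot(inherits(raw, "raw_channel_set"))
  extract <- if (kind == "respiration") extract_respiration else
    extract_heartbeat
  bands <- band_spec(kind)
  nm <- names(raw$channels)
  snrs <- rep(NA_real_, length(nm)); names(snrs) <- nm
  waves <- vector("list", length(nm))
  for (i in seq_along(nm)) {
    w <- tryCatch(extract(raw$channels[[i]], raw$fs), error = function(e) NULL)
    if (is.null(w)) next
    s <- tryCatch(compute_snr(w, bands = bands), error = function(e) NULL)
    if (is.null(s)) next
    snrs[i] <- s$snr_db
    waves[[i]] <- w
  }
  if (all(is.na(snrs)))
    stop("all channels degenerate: no ", kind, " waveform could be extracted")
  best <- which.max(snrs)              # first index wins exact ties
  w <- waves[[best]]
  w$source_channel <- nm[best]
  w$snr_db <- snrs[[best]]
  attr(w, "all_snr_db") <- snrs
  w
}

#' Re-filter a heartbeat waveform around its second harmonic
#'
#' Estimates the dominant heart-rate frequency from the periodogram peak in
#' the HR band (0.75--1.92 Hz) and applies a zero-phase band-pass centred at
#' twice that frequency with half-width `halfwidth` Hz. The sharper second
#' harmonic is what beat timing is measured on.
#'
#' @param heartbeat a `vital_waveform` of kind `"heartbeat"`.
#' @param halfwidth band half-width, Hz; wide enough to admit HR variability
#'   while excluding the fundamental.
#' @param peak_ratio required ratio of the PSD peak to the in-band median
#'   power; below it the HR is declared undetectable.
#' @return a `vital_waveform` of kind `"heartbeat_h2"` with field `f_dom`.
#' @export
refilter_second_harmonic <- function(heartbeat, halfwidth = 0.6,
                                     peak_ratio = 10) {
  stopifnot(inherits(heartbeat, "vital_waveform"))
  if (heartbeat$kind != "heartbeat")
    stop("input must be a heartbeat vital_waveform")
  fs <- heartbeat$fs
  f_dom <- dominant_frequency(heartbeat$samples, fs, 0.75, 1.92,
                              ratio = peak_ratio)
  if (is.null(f_dom))
    stop("no dominant heart rate: PSD peak in [0.75, 1.92] Hz not above ",
         "noise floor")
  band <- c(max(2 * f_dom - halfwidth, 0.1), min(2 * f_dom + halfwidth,
                                                 fs / 2 * 0.98))
  bp <- signal::butter(4, band / (fs / 2), type = "pass")
  # the second harmonic sits above the heartbeat low-pass cutoff, so re-filter
  # the wideband (high-passed only) copy of the selected channel when present
  src <- heartbeat$wideband %||% heartbeat$samples
  y <- filt_zerophase_iir(bp, src, fs, pad_s = 10)
  new_vital_waveform(y, fs, "heartbeat_h2",
                     source_channel = heartbeat$source_channel,
                     snr_db = heartbeat$snr_db,
                     extras = list(f_dom = f_dom))
}
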