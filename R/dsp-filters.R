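# Filter design and zero-phase application.
#
# All filtering in the analysis chain is zero-phase: extrema timing feeds the
# inter-beat and breath-interval estimates, and phase distortion would bias
# them. IIR filters are applied forward-backward; linear-phase FIR filters are
# applied once with their integer group delay removed. Both use odd-reflection
# end padding to suppress edge transients.

#' Design the respiration baseline-removal high-pass filter
#'
#' Order-5 Butterworth high-pass with a 3 dB cutoff of 0.05 Hz, used to strip
#' slow baseline drift before respiration extraction.
#'
#' @param fs sampling rate, Hz.
#' @param f3db 3 dB cutoff, Hz.
#' @return an `Arma` filter object (from the signal package).
#' @export
design_resp_highpass <- function(fs = 100, f3db = 0.05) {
  signal::butter(5, f3db / (fs / 2), type = "high")
}

#' Design the heartbeat extraction high-pass filter
#'
#' Third-order Butterworth high-pass with a 3 dB cutoff of 0.7 Hz, removing
#' respiration and drift ahead of heartbeat extraction.
#'
#' @inheritParams design_resp_highpass
#' @return an `Arma` filter object.
#' @export
design_heart_highpass <- function(fs = 100, f3db = 0.7) {
  signal::butter(3, f3db / (fs / 2), type = "high")
}

# Kaiser-window FIR low-pass: 60 dB stopband, 0.2 Hz transition by default.
# The order is rounded up to even so the group delay is an integer.
design_kaiser_lowpass <- function(fc, fs = 100, trans = 0.2, atten_db = 60) {
  dev <- 10^(-atten_db / 20)
  ko <- signal::kaiserord(c(fc, fc + trans), c(1, 0), c(dev, dev), fs)
  n <- ko$n + (ko$n %% 2)
  signal::fir1(n, ko$Wc, type = "low",
               window = signal::kaiser(n + 1, ko$beta))
}

# Odd-reflection padding of length P at both ends.
pad_reflect <- function(x, P) {
  n <- length(x)
  P <- min(P, n - 1L)
  c(2 * x[1] - rev(x[2:(P + 1)]), x, 2 * x[n] - rev(x[(n - P):(n - 1)]))
}

# One-sided AR (linear-prediction) forecast of length P from the end of x.
ar_forecast <- function(x, P, order = 60) {
  n <- length(x)
  order <- min(order, n - 1L)
  fit <- tryCatch(stats::ar(x, aic = FALSE, order.max = order,
                            method = "yule-walker", demean = TRUE),
                  error = function(e) NULL)
  if (is.null(fit) || !length(fit$ar)) return(NULL)
  co <- fit$ar
  p <- length(co)
  buf <- c(x[(n - p + 1):n] - fit$x.mean, numeric(P))
  for (i in seq_len(P))
    buf[p + i] <- sum(co * buf[(p + i - 1):(p + i - p)])
  buf[(p + 1):(p + P)] + fit$x.mean
}

# End padding by AR extrapolation (smooth continuation of tones and
# quasi-periodic vitals; no curvature kink at the record edge), falling back
# to odd reflection for degenerate inputs.
pad_signal <- function(x, P) {
  n <- length(x)
  P <- min(P, n - 1L)
  if (sd(x) < 1e-14) return(c(rep(x[1], P), x, rep(x[n], P)))
  fwd <- ar_forecast(x, P)
  bwd <- ar_forecast(rev(x), P)
  if (is.null(fwd) || is.null(bwd)) return(pad_reflect(x, P))
  c(rev(bwd), x, fwd)
}

# Zero-phase IIR: AR-extrapolated pad, filter forward then backward.
filt_zerophase_iir <- function(filt, x, fs, pad_s = 60) {
  n <- length(x)
  P <- min(n - 1L, round(pad_s * fs))
  y <- as.numeric(signal::filter(filt, pad_signal(x, P)))
  y <- rev(as.numeric(signal::filter(filt, rev(y))))
  y[(P + 1):(P + n)]
}

# Zero-phase linear-phase FIR: symmetric convolution, group delay removed.
filt_zerophase_fir <- function(b, x) {
  n <- length(x)
  d <- (length(b) - 1L) %/% 2L
  xp <- pad_signal(x, d)
  y <- stats::convolve(xp, rev(b), type = "open")
  y[(2 * d + 1):(2 * d + n)]
}

#' Magnitude response of a designed filter
#'
#' Evaluates `|H(f)|` of an IIR (`Arma`/list with `b`, `a`) or FIR (numeric
#' coefficient vector) filter on the given frequency grid. This is the
#' single-pass response; the analysis chain applies filters zero-phase, which
#' squares the magnitude.
#'
#' @param filt filter object or FIR coefficient vector.
#' @param f frequencies to evaluate, Hz.
#' @param fs sampling rate, Hz.
#' @return numeric vector of `|H(f)|`.
#' @export
filter_magnitude <- function(filt, f, fs = 100) {
  if (is.numeric(filt)) { b <- filt; a <- 1 }
  else { b <- filt$b; a <- filt$a }
  w <- exp(-1i * 2 * pi * f / fs)
  num <- vapply(seq_along(f), function(i) sum(b * w[i]^(seq_along(b) - 1)),
                complex(1))
  den <- vapply(seq_along(f), function(i) sum(a * w[i]^(seq_along(a) - 1)),
                complex(1))
  Mod(num / den)
}

#' Locate the -3 dB crossing of a filter's magnitude response
#'
#' Scans a dense frequency grid over `[f_lo, f_hi]` and returns the frequency
#' at which the single-pass magnitude response crosses 1/sqrt(2), by linear
#' interpolation between grid points.
#'
#' @param filt filter object or FIR coefficients (see [filter_magnitude()]).
#' @param fs sampling rate, Hz.
#' @param f_lo,f_hi search interval, Hz.
#' @param n grid size.
#' @return crossing frequency, Hz.
#' @export
find_f3db <- function(filt, fs = 100, f_lo = 1e-3, f_hi = 5, n = 20000) {
  f <- seq(f_lo, f_hi, length.out = n)
  m <- filter_magnitude(filt, f, fs)
  target <- 1 / sqrt(2)
  s <- sign(m - target)
  idx <- which(s[-1] != s[-n])[1]
  if (is.na(idx)) stop("no -3 dB crossing in the search interval")
  f1 <- f[idx]; f2 <- f[idx + 1]; m1 <- m[idx]; m2 <- m[idx + 1]
  f1 + (target - m1) * (f2 - f1) / (m2 - m1)
}
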