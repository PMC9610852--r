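#' Moving-average-crossing (MAC) peak detection
#'
#' Computes a centred moving average of length `window` and uses the
#' upward/downward crossing pairs of the signal against it to delimit
#' candidate regions; the maximum sample inside each enclosed region is a
#' peak. Regions touching the record boundary (no enclosing crossing pair)
#' are discarded, and peaks closer than a refractory interval are merged,
#' keeping the larger (earlier on exact ties).
#'
#' @param x numeric samples or a `waveform`.
#' @param fs sampling rate, Hz.
#' @param window moving-average length, s (>= 2 samples).
#' @param refractory merge interval, s; defaults to half the window.
#' @param min_region minimum above-MAC region width, s; shorter regions are
#'   treated as noise fragments around a crossing and discarded. Defaults to
#'   a tenth of the window.
#' @param smooth moving-average width, s, applied only when locating the
#'   maximum inside each region (robust peak timing under wideband noise; the
#'   crossing structure itself uses the raw signal). Defaults to half the
#'   window; set 0 to take the raw argmax, appropriate for signals that are
#'   already narrowband or whose peaks are asymmetric.
#' @param min_prominence relative prominence floor: peaks rising above the MAC
#'   by less than this fraction of the median peak-above-MAC height are
#'   discarded (suppresses residual baseline wiggle on otherwise quiescent
#'   stretches). 0 disables the rule.
#' @param t0 time of the first sample, s.
#' @return numeric vector of peak times, s.
#' @export
mac_peaks <- function(x, fs = 100, window, refractory = window / 2,
                      min_region = window / 10, smooth = window / 2,
                      min_prominence = 0, t0 = 0) {
  if (inherits(x, "waveform")) { fs <- x$fs; t0 <- x$t0; x <- x$samples }
  n <- length(x)
  nw <- round(window * fs)
  if (nw < 2) stop("window must span at least 2 samples")
  if (nw > n) stop("window longer than record")
  run_mean <- function(v, half) {
    cs <- cumsum(c(0, v))
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  mac <- run_mean(x, nw %/% 2L)
  ns <- round(smooth * fs) %/% 2L
  xs <- if (ns >= 1) run_mean(x, ns) else x
  above <- x > mac
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & starts > 1L & ends < n &   # enclosed by both crossings
    r$lengths >= max(1L, round(min_region * fs))
  if (!any(keep)) return(numeric(0))
  idx <- mapply(function(s, e) s - 1L + which.max(xs[s:e]),
                starts[keep], ends[keep])
  idx <- sort(idx)
  # refractory merge, larger amplitude wins (earlier on ties)
  merged <- idx[1]
  for (i in idx[-1]) {
    last <- merged[length(merged)]
    if ((i - last) / fs < refractory) {
      if (xs[i] > xs[last]) merged[length(merged)] <- i
    } else merged <- c(merged, i)
  }
  if (min_prominence > 0 && length(merged) > 1) {
    prom <- x[merged] - mac[merged]
    merged <- merged[prom >= min_prominence * median(prom)]
  }
  t0 + (merged - 1L) / fs
}

new_beat_series <- function(time, ibi, flags = NULL) {
  stopifnot(length(time) == length(ibi), !is.unsorted(time, strictly = TRUE),
            all(ibi > 0, na.rm = TRUE))
  out <- data.frame(time = time, ibi = ibi,
                    flag = flags %||% rep("ok", length(time)))
  class(out) <- c("beat_series", "data.frame")
  out
}

#' Beat detection on the second-harmonic heartbeat waveform
#'
#' Runs [mac_peaks()] on the second-harmonic waveform (two peaks per
#' heartbeat) and measures each inter-beat interval as the time for two
#' cycles: `ibi[k] = peak[k+2] - peak[k]`, timestamped at the first peak of
#' the pair. By default the spans overlap (one interval per harmonic peak),
#' maximizing tachogram resolution; `overlap = FALSE` uses disjoint pairs.
#'
#' @param h2 a `vital_waveform` of kind `"heartbeat_h2"` (see
#'   [refilter_second_harmonic()]).
#' @param window MAC window, s; defaults to 0.75 of the second-harmonic
#'   period, estimated from the waveform's dominant frequency.
#' @param overlap use overlapping two-cycle spans (default) or disjoint pairs.
#' @param edge_guard discard peaks within this many seconds of the record
#'   ends (zero-phase filter edge transients); default 1 s.
#' @return a `beat_series` data frame with columns `time`, `ibi`, `flag`.
#' @export
detect_ibi <- function(h2, window = NULL, overlap = TRUE, edge_guard = 1) {
  stopifnot(inherits(h2, "vital_waveform"))
  if (h2$kind != "heartbeat_h2")
    stop("detect_ibi expects a heartbeat_h2 waveform")
  if (is.null(window)) {
    f_h2 <- if (!is.null(h2$f_dom)) 2 * h2$f_dom else
      dominant_frequency(h2$samples, h2$fs, 1.5, 3.9) %||%
      stop("cannot estimate the second-harmonic rate")
    window <- 0.75 / f_h2
  }
  pk <- mac_peaks(h2$samples, h2$fs, window, t0 = h2$t0)
  t_end <- h2$t0 + (length(h2$samples) - 1) / h2$fs
  pk <- pk[pk >= h2$t0 + edge_guard & pk <= t_end - edge_guard]
  if (length(pk) < 3) stop("fewer than 3 second-harmonic peaks detected")
  k <- if (overlap) seq_len(length(pk) - 2L) else
    seq(1L, length(pk) - 2L, by = 2L)
  new_beat_series(pk[k], pk[k + 2L] - pk[k])
}

#' Inspire-end detection on a respiration waveform
#'
#' MAC peak detection with the window tied to the dominant respiration period
#' (0.7 of it, from the periodogram peak in the respiration band). Maxima of
#' the respiration trace are the inspire-end points `te`. A record with no
#' detectable respiration rhythm returns an empty vector, not an error.
#'
#' @param resp a `vital_waveform` of kind `"respiration"`.
#' @param window MAC window, s; default `0.7 / f_dom`.
#' @param edge_guard discard peaks within this many seconds of the record
#'   ends, where zero-phase filtering leaves edge transients; defaults to one
#'   MAC window.
#' @return ascending numeric vector of inspire-end times, s.
#' @export
detect_inspire_end <- function(resp, window = NULL, edge_guard = NULL) {
  stopifnot(inherits(resp, "vital_waveform"))
  if (resp$kind != "respiration")
    stop("detect_inspire_end expects a respiration waveform")
  if (sd(resp$samples) < 1e-12) return(numeric(0))
  if (is.null(window)) {
    f_dom <- dominant_frequency(resp$samples, resp$fs, 0.1, 0.7, ratio = 3)
    if (is.null(f_dom)) return(numeric(0))
    window <- 0.7 / f_dom
  }
  if (round(window * resp$fs) > length(resp$samples)) return(numeric(0))
  # respiration is already narrowband and its peaks are asymmetric: take the
  # raw in-region argmax (smoothing would bias te toward the slow limb); the
  # prominence floor rejects baseline wiggle on quiescent stretches
  pk <- mac_peaks(resp$samples, resp$fs, window, smooth = 0,
                  min_prominence = 0.25, t0 = resp$t0)
  g <- edge_guard %||% window
  t_end <- resp$t0 + (length(resp$samples) - 1) / resp$fs
  pk[pk >= resp$t0 + g & pk <= t_end - g]
}

#' Refined inspire-begin detection
#'
#' For each consecutive inspire-end pair `(te[k-1], te[k])`, collects
#' candidate minima strictly inside the interval: zero crossings of the first
#' derivative (ZC1) and upward zero crossings of the second derivative whose
#' first derivative is close to zero (ZC2+0, `|r'| <= eps_slope`). Candidates
#' must have positive depth `d(b) = r(te[k]) - r(b)`. If the candidate depths
#' are comparable (max/min < 2, "all are minima"), the candidate closest to
#' the inspire-end is taken -- this lands on the end, not the start, of a flat
#' end-expiratory pause; otherwise the deepest candidate (minimum `r`) is
#' taken. Derivatives are computed on a lightly smoothed copy
#' (Savitzky--Golay) because raw double differentiation is noise-dominated.
#'
#' @param resp a `vital_waveform` of kind `"respiration"`.
#' @param te ascending inspire-end times from [detect_inspire_end()].
#' @param eps_frac slope tolerance as a fraction of the interval's 95th
#'   percentile of `|r'|`.
#' @param sg_frame_s Savitzky--Golay smoothing frame, s.
#' @param depth_ratio threshold on max/min candidate depth separating the
#'   "comparable depths" branch from the "deepest wins" branch.
#' @return numeric vector of length `length(te) - 1`: `tb[j]` lies in
#'   `(te[j], te[j+1])` and is `NA` when the interval had no admissible
#'   candidate (breath dropped downstream).
#' @export
detect_inspire_begin <- function(resp, te, eps_frac = 0.05, sg_frame_s = 0.5,
                                 depth_ratio = 2) {
  stopifnot(inherits(resp, "vital_waveform"))
  if (length(te) < 2) stop("need at least 2 inspire-end points")
  fs <- resp$fs
  nsg <- round(sg_frame_s * fs)
  if (nsg %% 2 == 0) nsg <- nsg + 1
  s <- if (nsg >= 5 && nsg < length(resp$samples))
    as.numeric(signal::sgolayfilt(resp$samples, p = 3, n = nsg))
  else resp$samples
  n <- length(s)
  r1 <- c(0, (s[3:n] - s[1:(n - 2)]) / 2, 0)
  r2 <- c(0, (r1[3:n] - r1[1:(n - 2)]) / 2, 0)
  t_idx <- function(tt) round((tt - resp$t0) * fs) + 1
  tb <- rep(NA_real_, length(te) - 1)
  for (j in seq_len(length(te) - 1)) {
    i0 <- t_idx(te[j]); i1 <- t_idx(te[j + 1])
    lo <- i0 + 2L; hi <- i1 - 2L            # strictly interior
    if (hi - lo < 3) next
    seg <- lo:(hi - 1L)
    zc1 <- seg[r1[seg] * r1[seg + 1L] < 0 | (r1[seg] != 0 & r1[seg + 1L] == 0)]
    eps <- eps_frac * quantile(abs(r1[lo:hi]), 0.95, names = FALSE)
    zc2 <- seg[r2[seg] < 0 & r2[seg + 1L] >= 0 & abs(r1[seg]) <= eps]
    cand <- sort(unique(c(zc1, zc2)))
    if (!length(cand)) next
    depth <- s[i1] - s[cand]
    cand <- cand[depth > 0]; depth <- depth[depth > 0]
    if (!length(cand)) next
    pick <- if (max(depth) / min(depth) < depth_ratio)
      cand[which.min(abs(cand - i1))]       # closest to inspire-end
    else cand[which.min(s[cand])]           # deepest
    tb[j] <- resp$t0 + (pick - 1L) / fs
  }
  tb
}

#' Assemble a per-breath series from inspire-end and inspire-begin points
#'
#' Computes, per breath `k` (ending at `te[k]`): inter-respiration interval
#' `iri = te[k] - te[k-1]`, inspiratory interval `ii = te[k] - tb[k]`,
#' expiratory interval `ei = tb[k] - te[k-1]` and inspiratory volume proxy
#' `iv = r(te[k]) - r(tb[k])`. Breaths violating the timing invariants (or
#' with a missing `tb`) are dropped and flagged, not fatal.
#'
#' @param resp a `vital_waveform` of kind `"respiration"` (used to read the
#'   amplitude at `te`/`tb`).
#' @param te ascending inspire-end times.
#' @param tb inspire-begin times: either length `length(te) - 1` (interval
#'   `j` holds `tb` of the breath ending at `te[j+1]`, `NA` allowed) or
#'   length `length(te)` (paired elementwise, `tb[k] < te[k]`; the first
#'   breath has no predecessor and is not emitted).
#' @return data frame of class `breath_series` with columns `tb`, `te`,
#'   `r_tb`, `r_te`, `iri`, `ii`, `ei`, `iv`; attribute `n_dropped` counts
#'   excluded breaths.
#' @export
build_breath_series <- function(resp, te, tb) {
  stopifnot(inherits(resp, "waveform"))
  K <- length(te)
  if (length(tb) == K) tb <- tb[-1]
  if (length(tb) != K - 1)
    stop("tb must have length(te) or length(te) - 1 entries")
  val <- function(tt) resp$samples[pmin(pmax(round((tt - resp$t0) * resp$fs)
                                             + 1, 1), length(resp$samples))]
  te_prev <- te[-K]; te_k <- te[-1]
  iri <- te_k - te_prev
  ii <- te_k - tb
  ei <- tb - te_prev
  r_te <- val(te_k); r_tb <- val(tb)
  iv <- r_te - r_tb
  ok <- !is.na(tb) & ii > 0 & ei > 0 & iv > 0
  out <- data.frame(tb = tb[ok], te = te_k[ok], r_tb = r_tb[ok],
                    r_te = r_te[ok], iri = iri[ok], ii = ii[ok], ei = ei[ok],
                    iv = iv[ok])
  attr(out, "n_dropped") <- sum(!ok)
  class(out) <- c("breath_series", "data.frame")
  out
}

#' Full breath detection on a respiration waveform
#'
#' Convenience wrapper: [detect_inspire_end()], [detect_inspire_begin()],
#' [build_breath_series()].
#'
#' @inheritParams detect_inspire_begin
#' @param ... passed to [detect_inspire_begin()].
#' @return a `breath_series` (empty when fewer than 2 inspire-ends).
#' @export
detect_breaths <- function(resp, ...) {
  te <- detect_inspire_end(resp)
  if (length(te) < 2)
    return(structure(data.frame(tb = numeric(0), te = numeric(0),
                                r_tb = numeric(0), r_te = numeric(0),
                                iri = numeric(0), ii = numeric(0),
                                ei = numeric(0), iv = numeric(0)),
                     n_dropped = 0L,
                     class = c("breath_series", "data.frame")))
  tb <- detect_inspire_begin(resp, te, ...)
  build_breath_series(resp, te, tb)
}
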