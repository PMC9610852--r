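#' Sliding-epoch specification
#'
#' Epochs are half-open `[start, start + twin)` windows advanced by `tslide`,
#' with the first `reject_head` seconds of the routine rejected (settling
#' period).
#'
#' @param twin epoch length, s (default 90).
#' @param tslide slide interval, s (default 10); must satisfy
#'   `twin > tslide > 0`.
#' @param reject_head rejected settling period at the start of the routine, s.
#' @return object of class `epoch_spec`.
#' @export
epoch_spec <- function(twin = 90, tslide = 10, reject_head = 10) {
  if (!(twin > tslide && tslide > 0))
    stop("need twin > tslide > 0")
  stop_if_not_scalar(reject_head, "reject_head", 0)
  structure(list(twin = twin, tslide = tslide, reject_head = reject_head),
            class = "epoch_spec")
}

#' Enumerate epochs over a routine
#'
#' Epoch starts are `reject_head, reject_head + tslide, ...` for as long as
#' the whole epoch fits in the record (`start + twin <= duration`).
#'
#' @param duration routine length, s.
#' @param spec an [epoch_spec()].
#' @return data frame with columns `start`, `end` (half-open intervals); empty
#'   with a warning when the record is shorter than one epoch.
#' @export
make_epochs <- function(duration, spec = epoch_spec()) {
  stopifnot(inherits(spec, "epoch_spec"))
  if (duration - spec$reject_head < spec$twin) {
    warning("record shorter than one epoch: no epochs generated")
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  starts <- seq(spec$reject_head, duration - spec$twin, by = spec$tslide)
  data.frame(start = starts, end = starts + spec$twin)
}

#' Reject implausible inter-beat intervals
#'
#' Removes IBI outside the physiological band (45--115 beats/min, i.e.
#' `[60/115, 60/45]` s) and IBI deviating more than `max_dev` (default 30%)
#' from the running median of `med_k` (default 7) neighbours.
#'
#' @param beats a `beat_series`.
#' @param max_dev maximum relative deviation from the running median.
#' @param med_k running-median width (odd).
#' @param hr_range admissible heart-rate range, beats/min.
#' @return the cleaned `beat_series`; attribute `n_rejected` counts removals.
#' @export
clean_ibi <- function(beats, max_dev = 0.3, med_k = 7,
                      hr_range = c(45, 115)) {
  stopifnot(inherits(beats, "beat_series") || is.data.frame(beats))
  ibi <- beats$ibi
  in_range <- ibi >= 60 / hr_range[2] & ibi <= 60 / hr_range[1]
  med <- if (length(ibi) >= med_k) stats::runmed(ibi, med_k) else
    rep(median(ibi), length(ibi))
  near_med <- abs(ibi - med) <= max_dev * med
  keep <- in_range & near_med & !is.na(ibi)
  out <- beats[keep, , drop = FALSE]
  attr(out, "n_rejected") <- sum(!keep)
  class(out) <- c("beat_series", "data.frame")
  out
}

#' Lomb--Scargle band power of an unevenly sampled series
#'
#' Classic normalized Lomb--Scargle periodogram evaluated on a uniform
#' frequency grid (4x oversampled relative to `1/T`), integrated over
#' `[f_lo, f_hi]`. Used for the LF/HF tachogram powers on ultra-short epochs,
#' where interpolation artifacts are to be avoided.
#'
#' @param times sample times, s (need not be uniform).
#' @param y sample values.
#' @param f_lo,f_hi band edges, Hz.
#' @param oversample frequency-grid oversampling factor.
#' @return band power (periodogram integrated over the band), >= 0.
#' @export
lomb_band_power <- function(times, y, f_lo, f_hi, oversample = 4) {
  stopifnot(length(times) == length(y), length(y) >= 4)
  y <- y - mean(y)
  T_span <- diff(range(times))
  df <- 1 / (oversample * T_span)
  f <- seq(max(f_lo, df), f_hi, by = df)
  if (!length(f)) return(0)
  p <- vapply(f, function(fi) {
    w <- 2 * pi * fi
    tau <- atan2(sum(sin(2 * w * times)), sum(cos(2 * w * times))) / (2 * w)
    ct <- cos(w * (times - tau)); st <- sin(w * (times - tau))
    0.5 * (sum(y * ct)^2 / sum(ct^2) + sum(y * st)^2 / sum(st^2))
  }, 1)
  sum(p) * df
}

# Interpolated-tachogram alternative: resample the IBI series at 4 Hz and
# integrate the rectangular-window periodogram over the band.
interp_band_power <- function(times, y, f_lo, f_hi, fs_i = 4) {
  g <- seq(min(times), max(times), by = 1 / fs_i)
  yi <- approx(times, y, xout = g)$y
  pg <- periodogram_power(yi - mean(yi), fs_i)
  sum(pg$power[pg$freq >= f_lo & pg$freq <= f_hi])
}

hrv_feature_names <- function() c("hr_mean", "ibi_mean", "ibi_sd", "pibi50",
                                  "lf", "hf", "lf_hf")

rwv_feature_names <- function() {
  base <- c("ii", "ei", "iri", "rr", "iv", "eii")
  c(paste0(rep(base, each = 2), c("_mean", "_sd")),
    as.vector(vapply(c("ii", "ei", "iri", "iv"), function(y)
      paste0(rep(paste0("sd", 1:2, "_", y), each = 3),
             c("_mean", "_sd", "_eta")), character(6))))
}

#' Canonical feature column order
#'
#' The 7 HRV feature names followed by the 36 RWV feature names, in the fixed,
#' versioned order used by [feature_matrix()] and the classifiers.
#'
#' @return character vector of length 43.
#' @export
feature_names <- function() c(hrv_feature_names(), rwv_feature_names())

#' Ultra-short HRV features for one epoch
#'
#' From the clean IBI falling in the half-open epoch (membership by beat
#' time): mean heart rate `mean(60/ibi)`, mean and sample standard deviation
#' of IBI, `pIBI50` (fraction of successive IBI differences exceeding 50 ms),
#' and the LF (0.04--0.15 Hz) and HF (0.15--0.4 Hz) tachogram band powers with
#' their ratio.
#'
#' @param beats a (cleaned) `beat_series`.
#' @param epoch numeric `c(start, end)`, s.
#' @param estimator spectral estimator for LF/HF: Lomb--Scargle on the uneven
#'   tachogram (default) or periodogram of the 4 Hz interpolated tachogram.
#' @param min_beats minimum clean IBI count; fewer raises an error (the epoch
#'   is dropped by the caller).
#' @param pibi50_denom denominator convention: successive-difference count
#'   (default) or total IBI count.
#' @return named numeric vector of length 7.
#' @export
hrv_features <- function(beats, epoch, estimator = c("lomb", "interp"),
                         min_beats = 10,
                         pibi50_denom = c("diff", "total")) {
  estimator <- match.arg(estimator)
  pibi50_denom <- match.arg(pibi50_denom)
  sel <- beats$time >= epoch[1] & beats$time < epoch[2]
  ibi <- beats$ibi[sel]; tt <- beats$time[sel]
  if (length(ibi) < min_beats)
    stop("too few clean IBI in epoch (", length(ibi), " < ", min_beats, ")")
  d <- diff(ibi)
  denom <- if (pibi50_denom == "diff") length(d) else length(ibi)
  bp <- if (estimator == "lomb") lomb_band_power else interp_band_power
  lf <- bp(tt, ibi, 0.04, 0.15)
  hf <- bp(tt, ibi, 0.15, 0.4)
  c(hr_mean = mean(60 / ibi), ibi_mean = mean(ibi), ibi_sd = sd(ibi),
    pibi50 = sum(abs(d) > 0.05) / denom, lf = lf, hf = hf,
    lf_hf = if (hf > 0) lf / hf else 0)
}

#' Respiration waveform variability features for one epoch
#'
#' From the breaths starting (at `te - iri`) inside the half-open epoch:
#' mean/sd of the per-breath II, EI, IRI, IV and EI/II series; a respiration
#' rate series `60 / mean(iri)` over consecutive non-overlapping 15 s blocks
#' (blocks without a complete IRI are excluded); and mean, sd and mean/sd
#' (eta) of the first and second successive differences (SD1, SD2) of II, EI,
#' IRI and IV. When an sd is zero the corresponding eta is set to 0
#' (degenerate variability preserved without infinities).
#'
#' @param breaths a `breath_series`.
#' @param epoch numeric `c(start, end)`, s.
#' @param rr_block respiration-rate estimation block, s.
#' @param min_breaths minimum breath count; fewer raises an error.
#' @return named numeric vector of length 36.
#' @export
rwv_features <- function(breaths, epoch, rr_block = 15, min_breaths = 4) {
  start <- breaths$te - breaths$iri
  sel <- start >= epoch[1] & start < epoch[2]
  b <- breaths[sel, , drop = FALSE]
  if (nrow(b) < min_breaths)
    stop("too few breaths in epoch (", nrow(b), " < ", min_breaths, ")")
  eta <- function(m, s) if (s > 0) m / s else 0
  sd0 <- function(x) { s <- sd(x); if (is.na(s)) 0 else s }
  # respiration rate over tiled blocks
  edges <- seq(epoch[1], epoch[2], by = rr_block)
  rr <- numeric(0)
  for (i in seq_len(length(edges) - 1)) {
    inb <- (b$te - b$iri) >= edges[i] & b$te <= edges[i + 1]
    if (any(inb)) rr <- c(rr, 60 / mean(b$iri[inb]))
  }
  if (!length(rr)) rr <- 60 / mean(b$iri)
  base <- list(ii = b$ii, ei = b$ei, iri = b$iri, rr = rr, iv = b$iv,
               eii = b$ei / b$ii)
  out <- unlist(lapply(base, function(x) c(mean = mean(x), sd = sd0(x))))
  names(out) <- paste0(rep(names(base), each = 2), c("_mean", "_sd"))
  for (ynm in c("ii", "ei", "iri", "iv")) {
    y <- base[[ynm]]
    for (i in 1:2) {
      d <- if (i == 1) diff(y) else diff(diff(y))
      m <- mean(d); s <- sd0(d)
      v <- c(m, s, eta(m, s))
      names(v) <- paste0("sd", i, "_", ynm, c("_mean", "_sd", "_eta"))
      out <- c(out, v)
    }
  }
  out[rwv_feature_names()]
}

#' Build the labelled epoch-feature table for one routine
#'
#' Enumerates epochs, cleans the beat series once, and joins the 7 HRV and 36
#' RWV features per epoch with the routine label and subject id. Epochs with
#' too few clean beats or breaths are dropped and logged.
#'
#' @param beats a `beat_series` for the routine.
#' @param breaths a `breath_series` for the routine.
#' @param duration analysed routine length, s.
#' @param spec an [epoch_spec()].
#' @param label routine label, `"R"` or `"A"`.
#' @param subject_id subject identifier.
#' @param ... passed to [hrv_features()].
#' @return data frame of class `epoch_features`: `subject_id`, `label`,
#'   `epoch_start` plus the 43 feature columns of [feature_names()];
#'   attribute `dropped` logs excluded epochs with reasons.
#' @export
feature_matrix <- function(beats, breaths, duration, spec = epoch_spec(),
                           label = "R", subject_id = "s1", ...) {
  epochs <- make_epochs(duration, spec)
  cleaned <- clean_ibi(beats)
  cleaned <- cleaned[order(cleaned$time), , drop = FALSE]
  breaths <- breaths[order(breaths$te), , drop = FALSE]
  rows <- vector("list", nrow(epochs))
  dropped <- character(0)
  for (i in seq_len(nrow(epochs))) {
    ep <- c(epochs$start[i], epochs$end[i])
    hv <- tryCatch(hrv_features(cleaned, ep, ...), error = function(e)
      conditionMessage(e))
    rv <- tryCatch(rwv_features(breaths, ep), error = function(e)
      conditionMessage(e))
    if (is.character(hv) || is.character(rv)) {
      reason <- paste(c(if (is.character(hv)) hv, if (is.character(rv)) rv),
                      collapse = "; ")
      dropped <- c(dropped, sprintf("epoch %g: %s", ep[1], reason))
      next
    }
    rows[[i]] <- c(hv, rv)
  }
  keep <- !vapply(rows, is.null, TRUE)
  feats <- do.call(rbind, rows[keep])
  out <- data.frame(subject_id = as.character(subject_id), label = label,
                    epoch_start = epochs$start[keep],
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(feats))
  attr(out, "dropped") <- dropped
  attr(out, "spec") <- spec
  class(out) <- c("epoch_features", "data.frame")
  out
}

#' @export
print.epoch_features <- function(x, ...) {
  cat(sprintf("epoch_features: %d epochs x %d features; labels: %s\n",
              nrow(x), ncol(x) - 3L,
              paste(sprintf("%s=%d", names(table(x$label)), table(x$label)),
                    collapse = ", ")))
  invisible(x)
}
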