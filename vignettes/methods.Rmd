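---
title: "Methods: cardiorespiratory attention analysis in vigilwave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cardiorespiratory attention analysis in vigilwave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vigilwave)
```

## Overview

`vigilwave` analyses four-channel near-field RF baseband recordings
(thorax/abdomen x amplitude/phase) for binary attention-state detection. The
pipeline is: vital-sign extraction with SNR-based channel selection ->
beat/breath event detection -> sliding-epoch feature tables (7 HRV + 36 RWV
features) -> one of three classification protocols -> vigilance-task
response statistics. A seeded synthetic generator supplies sessions with
ground truth, so every stage is verifiable by parameter recovery. This
vignette records the model assumptions, the tunable parameters, and the
numerical and design choices that were genuinely open.

## Signal preparation

Respiration is extracted with an order-5 Butterworth high-pass (3 dB cutoff
0.05 Hz) and a Kaiser-window FIR low-pass cut at 0.8 Hz; heartbeat with a
third-order Butterworth high-pass at 0.7 Hz and an FIR low-pass at 1.9 Hz.
These passbands admit 6–40 breaths/min and 45–115 beats/min. Each trace is
normalized by the mean and RMS of its first 60 s (records shorter than 60 s
fall back to the full record, with a warning) and resampled to a uniform
100 Hz by polyphase rational resampling.

Numerical choices:

* **Zero-phase filtering everywhere.** Extrema timing feeds interval
  estimates (IBI, II, EI, IRI); causal filtering would bias them by the
  group delay. IIR filters run forward–backward; linear-phase FIR filters
  are applied once with their integer group delay removed (the FIR order is
  rounded up to even).
* **End padding by AR extrapolation.** Finite records need padding before
  zero-phase filtering. Odd-reflection padding leaves a curvature kink at
  the record edge which the 0.05–0.08 Hz high-passes ring on (a broadband
  leak near −40 dB that, among other things, breaks the degenerate
  "noise-free tone" SNR case). Instead the ends are extended by a
  Yule–Walker AR(≤60) forecast, which continues tones and quasi-periodic
  vitals smoothly; degenerate inputs fall back to reflection.
* **Kaiser FIR design.** 60 dB stopband, 0.2 Hz transition width — enough to
  separate the respiration band (≤0.7 Hz) from the heartbeat fundamental
  (≥0.75 Hz) at practical filter lengths (~1800 taps at 100 Hz).
* **Idempotence.** Re-running the preparation on an already-prepared
  in-band tone reproduces it with no multiplicative drift (gain error
  < 1e-5); absolute sample agreement is limited to ~1e-4 RMS because edge
  transients perturb the 60 s calibration-window mean — an irreducible
  consequence of the first-60-seconds normalization rule on finite records.

## SNR scoring and channel selection

Each channel is scored as `10*log10(P_f1 / (P_f2 + P_f3))` on the
rectangular-window periodogram of the whole record after baseline removal at
0.08 Hz. Band membership on discrete bins follows the interval notation:
f1 closed, f2 closed-below/open-above, f3 open-below/closed-above. A
vanishing noise power returns a capped +100 dB with a flag rather than
infinity. Selection is computed once per session (not per epoch), and ties
break deterministically in the fixed order thorax_amp, thorax_phase,
abd_amp, abd_phase.

## Second-harmonic beat timing

The mechanical heartbeat waveform is smooth; its weaker but sharper second
harmonic gives better timing. The dominant heart-rate frequency f_dom is
estimated from the periodogram peak in [0.75, 1.92] Hz (declared absent if
the peak is under 10x the in-band median power), and a zero-phase band-pass
centred at 2·f_dom with half-width 0.6 Hz (configurable; wide enough for HR
variability, narrow enough to exclude the fundamental) isolates the second
harmonic. One subtlety: the heartbeat chain's 1.9 Hz low-pass removes the
second harmonic itself (2·HR spans ~1.8–3.8 Hz), so the heartbeat waveform
carries a `wideband` copy — high-passed and normalized but not low-passed —
and the re-filtering acts on that copy. IBI is then the time for two cycles
of the second-harmonic peak train (`peak[k+2] − peak[k]`), with overlapping
spans by default (one estimate per harmonic peak; disjoint pairs by flag).

## MAC extrema detection

Peaks are found from crossings of the signal against its centred moving
average (MAC): each enclosed above-MAC region contributes its maximum
sample. Parameters and defaults:

* window = 0.75 / f(second harmonic) for beats, 0.7 / f(respiration) for
  breaths — under one period, guaranteeing crossings;
* refractory merge at half the window (larger peak wins; earlier on ties);
* regions shorter than a tenth of the window are discarded as noise
  fragments around a crossing;
* a relative prominence floor (peaks rising above the MAC by less than 25%
  of the median prominence are discarded, respiration only) suppresses
  residual baseline wiggle on quiescent stretches such as a session tail;
* peak *timing* within a region uses a moving-average-smoothed copy (width
  = half window) for generic wideband signals, but the raw argmax for
  respiration, whose peaks are asymmetric (smoothing would bias t_e toward
  the slow expiratory limb);
* regions touching the record boundary are discarded, and detections within
  one window of the ends are dropped (zero-phase filter edge transients).

## Inspire-begin refinement

Between consecutive inspire-ends, candidate minima are the zero crossings of
the first derivative (ZC1) plus the upward zero crossings of the second
derivative with the first derivative close to zero (|r'| ≤ ε, ZC2+0).
Candidates must lie strictly inside the interval and have positive depth
d(b) = r(t_e) − r(b). If max(d)/min(d) < 2 (all candidates comparable — "all
are minima"), the candidate closest to the inspire-end wins; this lands on
the *end* of a flat end-expiratory pause rather than its start. Otherwise
the deepest candidate wins. Open parameters, decided and configurable:

* ε = 0.05 x the 95th percentile of |r'| within the interval (unit-free,
  robust to amplitude);
* derivatives are taken on a Savitzky–Golay-smoothed copy (order 3, 0.5 s
  frame) — raw double differencing of sampled data is noise-dominated;
* candidates exactly at the interval endpoints are inadmissible;
* an interval with no admissible candidate drops that breath with a flag.

The 0.5 s smoothing frame bounds the achievable t_b accuracy for pause
breaths at roughly ±0.2 s (the corner between a flat pause and the
inspiration onset is rounded over the frame); non-pause breaths recover t_b
to ~0.05–0.07 s.

## Features

Epochs are half-open 90 s windows advanced by 10 s, after rejecting a 10 s
settling head. Events belong to the epoch containing their start time (beat
time for an IBI; t_e − IRI for a breath). Clean IBI (within [60/115, 60/45]
s and within 30% of the running median of 7) feed: mean(HR), mean(IBI),
std(IBI), pIBI50, and LF/HF band powers. pIBI50's printed denominator
("total IBI count") is read as the successive-difference count — the analogue
of pNN50 — with the literal total-count reading available by configuration.
LF/HF powers come from a Lomb–Scargle periodogram of the uneven tachogram
(4x oversampled grid), avoiding interpolation artifacts on 90 s epochs; a
4 Hz interpolated-tachogram periodogram is available by configuration.
LF/HF is set to 0 when HF = 0.

The 36 RWV features are mean/std of II, EI, IRI, RR, IV, EI/II (12) and
mean, std, mean/std of the signed first and second successive differences of
II, EI, IRI, IV (24). RR is 60/mean(IRI) over six tiled (non-sliding) 15 s
blocks per epoch, excluding blocks without a complete IRI. When a std is 0
the mean/std ("eta") feature is set to 0 with the degenerate-variability
signal preserved. Epochs need ≥10 clean IBI and ≥4 breaths, else they are
dropped and logged.

## Classification protocols

* **Pooled 5-fold CV**: label-stratified, seeded, epochs pooled across
  subjects.
* **Leave-one-subject-out**: one fold per subject.
* **Personalized out-of-time**: per subject and routine, epochs fully inside
  the first 180 s of the *usable* (post-rejection) timeline train; epochs
  starting at or after 180 s test; straddling epochs are excluded, so train
  and test never overlap in time. With the default usable durations — 280 s
  relaxed (R), 380 s attention (A) — this yields 10 training epochs per
  routine and 2 R + 12 A test epochs per subject. kNN's k is tuned per
  subject on a seeded 50% holdout of the training epochs over {1,3,5,7,9},
  then refit on the full training split.

Features are z-scored with training-partition statistics only. Models: kNN
(k = 5 default, Euclidean on z-scores), RBF SVM, QDA (MASS, with a
diagonal-shrinkage Gaussian fallback when a class covariance is singular in
small personalized partitions), boosted trees (100 rounds) and bagged trees
(100 trees, all features per split). The **positive class is R**: with the
default epoch counts, per-subject sensitivity is the recall of the 2 R test
epochs and specificity the recall of the 12 A epochs — the assignment that
makes per-subject percentages like 8.3% (=1/12) arithmetically possible.
It is switchable.

The analysed durations default to 290 s (R) and 390 s (A) with the 10 s
settling rejection applied to both routines, giving the 280/380 s usable
spans and 20/30 epochs above. Session generation defaults to 300 s (R) and
390 s (A); the trailing R seconds are reserved.

## The synthetic generator: what it emulates, and what it does not

Breathing is drawn breath-by-breath: IRI around 60/mean_rr (rate sd mapped
by the delta method, truncated at 3σ, clipped to 6–40 breaths/min), II =
ii_fraction·IRI perturbed, amplitude with coefficient of variation iv_cv,
and a flat end-expiratory pause (probability pause_prob, duration
pause_dur) inserted before inspiration when the expiration leaves room. The
waveform is a raised-cosine inspiration and a raised-cosine expiration over
the non-pause span. The cosine expiration (rather than an exponential decay)
was chosen so that symmetric pause-free breathing reduces exactly to a
sinusoid — a useful analytic limit — while the pause still reproduces the
asymmetric flat-bottomed morphology that makes inspire-begin detection hard.
The last inspire-end is kept ~3/4 period clear of the record tail so edge
transients cannot cost a breath.

Heartbeat intervals follow IBI = (60/mean_hr)·(1 + lf_amp·sin(2π·0.1·t) +
hf_amp·sin(breath phase) + e), i.e. a Mayer-wave-like LF term, respiratory
sinus arrhythmia as the simplest mechanism that yields an HF tachogram peak
at the breathing rate, and truncated white noise with sd hr_sd/mean_hr. The
rendered heartbeat is sin(φ) + h2·sin(2φ) on the interpolated beat phase.
Channels mix respiration and heartbeat with per-channel gains (thorax
favours heartbeat, abdomen respiration), sub-0.05 Hz sinusoidal drift with
random phase, and white noise. Defaults: mean HR 59 beats/min (sd 1.5),
LF depth 0.03, RSA depth 0.04, h2 = 0.5; mean RR 14 breaths/min (sd 1.2),
ii_fraction 0.4, pauses p = 0.15 x 0.8 s, iv_cv 0.12 — a resting adult.

Cohorts draw each subject's relaxed baseline around cohort means with
between-subject spreads (e.g. 7 beats/min in mean HR) that deliberately
exceed the default R→A shift (+3 beats/min, +2 breaths/min, −0.05
ii_fraction, damped variability). No quantitative R→A effect sizes exist to
copy; these shifts are free generator inputs, not physiological estimates.
Their consequence is the documented protocol ordering: subject identity
dominates state in pooled feature space, so leave-one-subject-out degrades
while personalized models do not.

The responder model presses on jumps within a lognormal reaction time
(median 0.45 s, truncated at the 1 s maximum), misses with probability
0.08 and false-presses with probability 0.01; the clock advances one 3.6°
step per second with jump probability 0.1.

What the generator does **not** emulate: motion artifacts beyond drift and
white noise, sensor dropouts, non-stationary drowsiness drift within a
routine, correlated inter-channel noise, or any RF propagation physics.
Passing recovery tests therefore demonstrates algorithmic correctness under
the stated statistical structure, not robustness to real-world artifacts.

A caution the null case makes explicit: with *zero* state shift, pooled CV
and personalized protocols still exceed chance on cohort features, because
heavily overlapping 90 s/10 s epochs let a classifier memorize
session-specific realizations. This temporal-similarity confound is a
property of sliding-epoch protocols on short two-session designs, not of the
generator; the well-posed null checks are leave-one-subject-out (~50%) and
label permutation (~50%).

## Response statistics

Events are the correct (C), wrong (W) and missed (M) outcomes; PoCR =
C/(C+W+M). Event-locked heart-rate ratios use stimulus-locked windows
(pre 5 s, post 10 s), left-closed 100 ms reaction-time bins anchored at 0;
missed jumps carry the fixed maximum RT (they populate the last bin) but are
excluded from mean-RT statistics. Bland–Altman agreement pairs two event
series by nearest time within 0.5 s and reports Pearson's r, bias m =
mean(x−y) and limits of agreement m ± 1.96·sd(x−y).

## Problem sizes and runtime

The shipped test-suite experiments use 300 s sessions at 100 Hz, 20-session
recovery sweeps, and 20-subject truth-event cohorts (protocol-ordering
checks run on generator truth events — the ordering is a feature/protocol
property, and the waveform chain's fidelity is established separately by the
recovery sweep). The full suite runs in under two minutes on one CPU; the
default `run_pipeline()` (4 subjects, 8 rendered sessions) takes a few
seconds.

## Known limitations

* Session I/O is CSV-only (lossless full-precision text).
* t_b accuracy for pause breaths is bounded by the 0.5 s derivative
  smoothing frame (~0.2 s systematic early shift at the pause-inspiration
  corner).
* The SNR estimator uses a single whole-record periodogram; no averaging or
  per-epoch re-selection.
* Classification on overlapping epochs inflates pooled-CV estimates (see the
  null-case caution above); leave-one-subject-out is the honest
  generalization measure, and the personalized protocol the honest
  within-subject measure.
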