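---
title: "Cardiovascular autonomic markers: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cardiovascular autonomic markers: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepcardio)
```

`sleepcardio` implements the signal-processing chain used to track
cardiovascular autonomic state around partial sleep deprivation protocols:
heart rate variability (HRV) from orthostatic-test inter-beat intervals,
sequence-method baroreflex sensitivity (BRS) from continuous blood pressure,
photoplethysmogram (PPG) waveform parametrization with a modified
augmentation index, actigraphy-based sleep windowing, and the study-level
aggregation and effect-size scheme. This vignette documents the underlying
models, every tunable that matters, the synthetic generators the tests rely
on, and the numerical decisions taken where the design was genuinely open.

## Heart rate variability

Raw inter-beat (RR) series are first cleaned into normal-to-normal (NN)
series. An interval is flagged ectopic when it deviates from the median of
its 10 nearest unflagged neighbours (5 per side, truncated at the record
edges) by more than `rel_threshold` (default 0.30). The threshold is a
conventional choice, not a physiological constant, and is exposed as a
parameter; flags are assigned in a single pass against the input flags so
the reference median is well defined. Flagged intervals are replaced by a
cubic spline fitted over beat index rather than time: index-domain
interpolation preserves the series length, which the subsequent tachogram
resampling requires. Segments with 20% or more flagged beats are rejected
outright — interpolating that much data would fabricate variability.

The panel per posture segment is:

* mean HR = 60000 / mean(NN) in bpm;
* RMSSD = sqrt(mean(successive NN differences squared)) in ms;
* spectral powers pLF, pHF and total power in ms^2;
* normalized powers nLF = pLF / (pLF + pHF), nHF = 1 - nLF.

Spectra are computed on the NN tachogram resampled at 4 Hz by cubic spline
(beat times are the cumulative interval sums), with a Welch estimator:
250-sample segments, 50% overlap, per-segment mean removal, Hann taper with
power normalization. Window length, overlap and the 4-Hz rate follow the
orthostatic-test convention the package targets; the taper is not dictated
by that convention, and Hann is the standard Welch default. Band edges are
half-open — LF is [0.04, 0.15) Hz and HF is [0.15, 0.40) Hz — because the
printed ranges touch at 0.15 Hz and a tie-break is mandatory; a component at
exactly 0.15 Hz counts as HF. Total power is integrated over [0.003, 0.40)
Hz; the 0.003-Hz floor excludes DC and ultra-low-frequency leakage that a
3-6-minute segment cannot resolve anyway. Only per-segment mean removal is
applied (no polynomial detrending); both the bands and the detrending are
configuration. No standing-transition transient is trimmed by default: the
posture segments arrive as separate series and any trimming belongs to the
recording protocol, not the estimator.

A 250-sample window at 4 Hz means a segment must span at least 62.5 s;
shorter segments produce an explicit validation error, and inside
`analyze_orthostatic()` a failed segment yields a missing-value summary
carrying the reason instead of aborting the other posture.

## Baroreflex sensitivity

Systolic peaks are extracted from the pressure wave as prominent local
maxima with a 0.3-s refractory period (a 200-bpm ceiling; configurable);
SBP_n is the peak amplitude and IBI_n the time to the next peak. The
sequence method then scans for spontaneous baroreflex events: runs of at
least 3 beats where SBP and IBI change monotonically in the same direction,
every SBP step at least 1 mmHg and every IBI step at least 5 ms. A run is
validated when the SBP-IBI Pearson correlation reaches 0.85, its slope is
the least-squares regression of IBI (ms) on SBP (mmHg), and the BRS estimate
is the unweighted mean slope — undefined (not zero) when fewer than five
validated sequences exist. Candidates are *maximal* monotone runs, not all
qualifying sub-windows: sequences are counted as physiological events, and
sub-window counting would inflate the count that the five-sequence rule
gates on. The tests verify the detector against an exhaustive enumeration
oracle that applies the four rules window by window. SBP-IBI lag is 0 beats
(same-beat pairing) by default and exposed as `lag_beats`; lag scanning is a
known variant but not the default convention here.

The synthetic counterpart (`simulate_baro()`) alternates flat holds with
monotone pressure ramps and couples the IBI linearly with a known gain. The
default geometry — 8-beat ramps at 4 mmHg/beat separated by 4-beat holds —
comes from a design calculation: at the smallest gain the recovery study
exercises (5 ms/mmHg) the per-beat IBI change is gain x step = 20 ms, which
clears the 5-ms validation floor by roughly two standard deviations of a
step difference at the largest simulated noise (sd 5 ms gives step-difference
sd ~7.1 ms). A smaller step would let the validation thresholds censor the
noise distribution and bias the selected slopes upward; the geometry is part
of the simulated conditions, not a tuning knob. With zero noise every
embedded ramp is collinear, so the estimate equals the gain to machine
precision — a useful end-to-end identity test.

## PPG waveform and the modified augmentation index

Each pulse is described by its onset (foot), systolic peak, dicrotic notch
and diastolic peak. Timing features are tS (onset to systolic peak), tC
(systolic peak to notch), tD (notch to diastolic peak) and PI (onset to next
onset); amplitudes aS, aDic, aD are measured above the pulse's own onset
value, which makes the panel drift-robust without assuming any global
baseline. The per-pulse augmentation term is (aD - aDic) / (aS - aDic), and
the modified augmentation index mAI is its mean over pulses with a defined
term. The alternative reading of the diastolic time — notch to *next onset*
— is available as `td_mode = "to_next_onset"`; the default follows the
segment naming (systolic / catacrotic / diastolic) in listed order.

Delineation is two-stage. Beats are located on a zero-phase 0.5-10 Hz
band-passed copy using the *upstroke*: the systolic rise is several times
steeper than the diastolic one, so a slope threshold separates them where an
amplitude threshold cannot. Fiducials are then refined at a scale chosen by
the measured noise floor (median absolute deviation of the signal minus its
40-Hz low-pass):

* negligible noise: a 7-ms running mean — extrema stay sample-exact, and
  the noise-free generator-recovery test holds to +-2 samples and +-2%
  amplitude;
* appreciable noise: a zero-phase 15-Hz Butterworth low-pass.

The adaptive scale exists because the pulse extrema are *flat*: around the
diastolic peak the template curvature is of order 30 mV/s^2, so even
15-Hz-filtered broadband noise (derivative sd ~0.2 mV/s at 1% of aS) shifts
the pointwise extremum by several milliseconds — no local estimator can
localize that summit to 5 ms at that noise level. The package therefore
quotes, and its property tests enforce, noise-dependent accuracy: at a noise
sd of 1% of aS the onset and notch stay within 5 samples (1000 Hz), the
systolic peak within 8 and the diastolic peak within 15; at zero noise all
fiducials are within 2 samples. Amplitude read-off always happens on the
refinement signal at the detected indices.

The notch is found *after* the diastolic peak: the most prominent interior
maximum of the catacrotic segment is taken as the diastolic peak and the
notch is the minimum between the two peaks. This is equivalent to "most
prominent minimum between the peaks" but robust to noise wiggles on the
descent, where spurious local minima can outrank the notch on value. Pulses
without a distinct diastolic wave fall back to the second-derivative maximum
of the catacrotic limb and are flagged non-canonical; non-canonical pulses
(including edge-truncated ones) are excluded from all window means and their
count is reported.

Window summaries average the per-pulse panel over the last hour of sleep,
`[wake - 3600 s, wake]`, with the wake time supplied by the actigraphy
module; shorter sleep periods are processed whole and flagged
`window_short`, and windows with fewer than `min_pulses` (default 100)
canonical pulses are flagged `low_quality` rather than suppressed.

## Actigraphy sleep window

The triaxial wrist signal is reduced to 5-s epochs: arm angle
atan(median z / sqrt(median x^2 + median y^2)) and activity (mean absolute
deviation of the acceleration norm from its epoch median). Epochs whose
angle change from the previous epoch stays below 5 degrees, sustained for at
least 5 min, are "still"; still blocks separated by less than 10 min are
bridged; sleep onset is the start of the first merged block of at least
30 min and wake the end of the last. These are the conventional published
arm-angle defaults, all exposed as configuration; with no qualifying block
the result is an explicit empty window. The detector's only job in this
pipeline is to hand the PPG module an (onset, wake) pair — it does not score
within-night sleep and wake.

## Study aggregation and effect sizes

Daily measurements are labelled by phase — baseline (BSL, 7 d), sleep
deprivation (SDP, 3 d), recovery (RCV, 7 d) — and aggregated per participant
and metric: BSL is the mean of available baseline days, SDP1-3 and RCV1-2
pass through unaveraged, and RCV3-7 is the mean of recovery days 3-7.
Missing days shrink the mean's denominator and are reported as
`n_days / n_expected`; a participant with no baseline yields an explicit
missing cell. Cohen's d uses the pooled standard deviation with the
(n1 + n2 - 2) denominator — the standard reading of "combined SD" — and the
size categories small (|d| < 0.20), medium (0.20 <= |d| < 0.80) and large
(|d| >= 0.80), computed on |d| so that swapping groups cannot change the
category. Effect sizes are computed on participant-level time-point means,
not pooled raw days. PVT summaries are the mean and sample SD of reaction
times after discarding false starts below 100 ms (the standard PVT floor,
configurable). Mixed-effects modelling and post-hoc testing are deliberately
out of scope: `phase_aggregate()` emits a tidy long table ready for any
external fitter.

## What the generators emulate — and what they do not

Every estimator is validated against a generator with analytic truth:

* `simulate_rr()` — NN series with sinusoidal LF/HF modulation (band powers
  A^2/2), optional white noise, and premature-beat contamination in which a
  randomly chosen beat is displaced so the two surrounding intervals become
  a 0.6x/1.4x short-long pair with their sum preserved;
* `simulate_baro()` — the ramp-hold pressure profile above with linear
  IBI coupling;
* `simulate_ppg()` — piecewise raised-cosine pulses whose local extrema sit
  exactly at the declared fiducials (the reason for raised cosines over
  Gaussians);
* `simulate_actigraphy()` — a fixed gravity orientation with small jitter
  inside the sleep window, large random orientation excursions (resampled
  every ~6 s) plus motion noise outside it.

None of these model respiration, circadian drift, PPG motion artifacts,
arrhythmia beyond isolated premature beats, or device quantization. Passing
tests therefore demonstrate estimator correctness under the stated models,
not robustness to every failure mode of real recordings; on real data the
configuration surface (thresholds, bands, refractory periods) is the
intended adaptation point.

## Problem sizes and runtime

The test and acceptance workloads are sized to run comfortably on one CPU:
300-s tachograms for the spectral oracles, 10-12-ramp pressure recordings
(~120-150 beats), 12-20-pulse PPG trains at 1000 Hz with longer surrogate
nights at 100 Hz, 8-h actigraphy at 25 Hz, and 100 random 300-beat series
for the sequence-detector enumeration oracle. These sizes are the package's
own choice of demonstration scale; all generators accept larger durations.

## Known limitations

* The Welch integral treats each frequency bin as belonging wholly to one
  band; with a 0.016-Hz bin width, tones within one bin of a band edge leak
  a few percent of their power across it.
* Sequence detection reports maximal runs only; literatures that count all
  qualifying sub-windows will report higher sequence counts from identical
  data.
* The PPG delineator assumes a single diastolic wave per pulse; bifid or
  heavily damped waveforms are flagged non-canonical rather than resolved.
* The actigraphy detector infers stillness, not sleep; quiet wakefulness at
  the window edges is attributed to sleep within the stated +-1-min
  tolerance.
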