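# sleepcardio

Cardiovascular autonomic markers around partial sleep deprivation, as a
tested R pipeline. Sleep restriction shifts the sympathovagal balance, and
that shift is visible in several cheap, non-invasive signals at once:
beat-to-beat heart rate variability (HRV), spontaneous baroreflex
sensitivity (BRS), and the shape of the photoplethysmogram (PPG) pulse.
`sleepcardio` implements the full chain from raw device exports to
study-level effect sizes, for researchers analysing orthostatic-test RR
recordings, continuous finger blood pressure, overnight wrist PPG and
actigraphy:

* **Beat preprocessing** — ectopic/artifact detection against a local
  10-beat median (default 30% deviation) and cubic-spline repair into
  normal-to-normal (NN) series; segments with >= 20% corrections are
  rejected.
* **HRV panel** per posture segment: mean HR, RMSSD, Welch band powers on
  the 4-Hz resampled tachogram (250-sample windows, 50% overlap, Hann) in
  the LF [0.04, 0.15) Hz and HF [0.15, 0.40) Hz bands, and normalized
  powers nLF = pLF/(pLF+pHF), nHF = 1 - nLF.
* **Sequence-method BRS**: maximal runs of >= 3 beats with concordant
  monotone SBP and inter-beat-interval changes (>= 1 mmHg and >= 5 ms per
  step, Pearson r >= 0.85); BRS (ms/mmHg) is the mean regression slope of
  IBI on SBP, valid only with >= 5 sequences.
* **PPG waveform panel**: per-pulse onset, systolic peak, dicrotic notch
  and diastolic peak; PI, tS, tC, tD, aS, aD, aDic; and the modified
  augmentation index `mAI = mean[(aD - aDic) / (aS - aDic)]`, averaged over
  the last hour of sleep.
* **Actigraphy sleep window**: arm-angle / activity epochs and still-block
  logic yielding the (sleep onset, wake) pair that anchors the PPG window.
* **Study aggregation**: BSL / SDP1-3 / RCV1 / RCV2 / RCV3-7 time points,
  Cohen's d with pooled SD (small < 0.20 <= medium < 0.80 <= large), and
  PVT reaction-time summaries.

Because raw study recordings are rarely redistributable, the package ships
synthetic generators for every input class — oscillatory NN series,
SBP-IBI recordings with a known gain, raised-cosine PPG pulse trains with
known fiducials, and actigraphy with a known still window — so every stage
is validated against analytic ground truth.

## Worked example

Simulate a 3-min orthostatic test with known spectral content (LF amplitude
30 ms at 0.10 Hz, HF amplitude 20 ms supine and 10 ms standing, 2% injected
premature beats), clean it, and compute the panel:

```r
library(sleepcardio)

supine_raw   <- simulate_rr(rr_sim_spec(hf_amp_ms = 20, mean_nn_ms = 1000,
                                        noise_sd_ms = 3, ectopic_rate = 0.02,
                                        duration_s = 180, seed = 21))
standing_raw <- simulate_rr(rr_sim_spec(hf_amp_ms = 10, mean_nn_ms = 800,
                                        noise_sd_ms = 3, ectopic_rate = 0.02,
                                        duration_s = 180, seed = 22))
panel <- analyze_orthostatic(orthostatic_test(clean_beats(supine_raw$beats),
                                              clean_beats(standing_raw$beats),
                                              protocol = "3-3"))
panel$supine
#> <hrv_summary> supine, 181 s
#>   HR 60.0 bpm | RMSSD 23.8 ms
#>   pLF 457.5  pHF 183.4  total 643.6 ms^2 | nLF 0.71  nHF 0.29
panel$standing
#> <hrv_summary> standing, 181 s
#>   HR 75.1 bpm | RMSSD 14.2 ms
#>   pLF 483.4  pHF 52.1  total 536.2 ms^2 | nLF 0.90  nHF 0.10
```

The supine powers sit on the analytic values (a sine of amplitude A carries
A^2/2 = 450 and 200 ms^2); halving the HF modulation while standing drops
pHF to about a quarter (52 vs 183 ms^2) and pushes nLF from 0.71 to 0.90 —
the classic vagal-withdrawal signature of standing up. Baroreflex gain is
recovered the same way:

```r
sim <- simulate_baro(baro_sim_spec(gain_ms_per_mmhg = 15,
                                   n_beats = baro_beats_for_ramps(10)))
estimate_brs(sim$beats)
#> <brs_estimate> valid: 15.00 ms/mmHg over 10 sequences (short recording)
```

The numbered scripts under `analysis/` walk the whole pipeline — signal
generation, HRV, BRS recovery across gains and noise levels, the
actigraphy-anchored last-hour PPG summary, and cohort-level aggregation —
writing their tables under `results/`.

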