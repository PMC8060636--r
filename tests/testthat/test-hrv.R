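# Time-domain indices, tachogram resampling, Welch band powers, and the
# orthostatic-test panel.

test_that("RMSSD and mean HR closed forms", {
  expect_equal(rmssd(c(800, 800, 800)), 0)
  expect_equal(rmssd(c(800, 850)), 50)
  expect_equal(rmssd(c(800, 900, 800, 900)), 100)  # sqrt(3*100^2/3)
  expect_error(rmssd(1000), class = "sc_validation_error")

  expect_equal(mean_hr(rep(1000, 10)), 60)
  expect_equal(mean_hr(rep(600, 10)), 100)
  expect_equal(mean_hr(c(500, 1500)), 60)
})

test_that("tachogram grid spans [first, last] beat time at the requested rate", {
  tach <- resample_nn(rep(1000, 60), fs_hz = 4)
  expect_equal(length(tach$values), 237)
  expect_equal(tach$fs, 4)
  expect_true(all(abs(tach$values - 1000) < 1e-9))
  expect_equal(diff(signal_times(tach))[1], 0.25)

  # spline through collinear (time, value) points reproduces the line
  nn <- numeric(80); t <- 0
  for (i in seq_along(nn)) {
    nn[i] <- (800 + 5 * t) / (1 - 0.005)  # value lies on 800 + 5 * t_beat
    t <- t + nn[i] / 1000
  }
  tach2 <- resample_nn(nn, fs_hz = 4)
  expect_equal(tach2$values, 800 + 5 * signal_times(tach2), tolerance = 1e-9)

  expect_error(resample_nn(rep(1000, 10)), class = "sc_validation_error")
})

test_that("band powers recover the analytic sine powers within 5%", {
  t <- seq(0, 300, by = 0.25)
  lf_only <- sampled_signal(1000 + 30 * sin(2 * pi * 0.10 * t), fs = 4)
  bp <- band_powers(lf_only)
  expect_equal(bp$pLF_ms2, 450, tolerance = 0.05)
  expect_lt(bp$pHF_ms2, 5)

  both <- sampled_signal(1000 + 30 * sin(2 * pi * 0.10 * t) +
                           20 * sin(2 * pi * 0.25 * t), fs = 4)
  bp2 <- band_powers(both)
  expect_equal(bp2$pHF_ms2, 200, tolerance = 0.05)
  expect_equal(bp2$nLF, 450 / 650, tolerance = 0.01)
  expect_equal(bp2$nLF + bp2$nHF, 1)
  # Parseval-type closure against the analytic total
  expect_equal(bp2$pLF_ms2 + bp2$pHF_ms2, 650, tolerance = 0.05)

  const <- band_powers(sampled_signal(rep(1000, 1201), fs = 4))
  expect_lt(const$pLF_ms2 + const$pHF_ms2 + const$totalPower_ms2, 1e-6)

  expect_error(band_powers(sampled_signal(rep(1000, 100), fs = 4)),
               "62.5", class = "sc_validation_error")
})

test_that("band edges are half-open: 0.15 Hz belongs to HF, not LF", {
  freq <- c(0.04, 0.1499, 0.15, 0.399, 0.40)
  lf <- sleepcardio:::band_mask(freq, c(0.04, 0.15))
  hf <- sleepcardio:::band_mask(freq, c(0.15, 0.40))
  expect_identical(lf, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_identical(hf, c(FALSE, FALSE, TRUE, TRUE, FALSE))
})

test_that("indices are stable to trimming a couple of seconds of identical beats", {
  sim <- simulate_rr(rr_sim_spec(duration_s = 300, seed = 21))
  nn <- sim$beats$intervals_ms
  padded <- c(rep(nn[1], 2), nn, rep(nn[length(nn)], 2))
  h1 <- hrv_summary(nn)
  h2 <- hrv_summary(padded)
  expect_equal(h2$RMSSD_ms, h1$RMSSD_ms, tolerance = 0.02)
  expect_equal(h2$pLF_ms2, h1$pLF_ms2, tolerance = 0.02)
  expect_equal(h2$pHF_ms2, h1$pHF_ms2, tolerance = 0.02)
})

test_that("the orthostatic panel is computed per posture with graceful failure", {
  su <- simulate_rr(rr_sim_spec(hf_amp_ms = 20, duration_s = 180, seed = 31))
  st <- simulate_rr(rr_sim_spec(hf_amp_ms = 10, duration_s = 180, seed = 32))
  test <- orthostatic_test(clean_beats(su$beats), clean_beats(st$beats), "3-3")
  res <- analyze_orthostatic(test)
  expect_equal(res$supine$posture, "supine")
  expect_equal(res$standing$posture, "standing")
  # halved HF modulation amplitude -> quarter HF power
  expect_equal(res$standing$pHF_ms2 / res$supine$pHF_ms2, 0.25, tolerance = 0.10)
  expect_equal(res$supine$nLF + res$supine$nHF, 1)

  # identical segments give identical summaries
  both <- analyze_orthostatic(orthostatic_test(su$beats$intervals_ms,
                                               su$beats$intervals_ms))
  expect_equal(both$supine$pLF_ms2, both$standing$pLF_ms2)

  # a too-short standing segment yields a flagged missing summary, not a crash
  broken <- analyze_orthostatic(orthostatic_test(su$beats$intervals_ms,
                                                 rep(800, 20)))
  expect_true(is.na(broken$standing$pLF_ms2))
  expect_match(broken$standing$failure_reason, "spans")
  expect_false(is.na(broken$supine$pLF_ms2))

  # 3-min protocol of 750-ms beats: 240 intervals per segment, panel defined
  seg <- rep(750, 240)
  panel <- analyze_orthostatic(orthostatic_test(seg, seg, "3-3"))
  expect_equal(panel$supine$meanHR_bpm, 80)
  expect_equal(panel$supine$segment_duration_s, 180)
})
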